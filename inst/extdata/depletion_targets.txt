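# six most abundant plasma proteins targeted for immunodepletion
ALB
IGHG1
IGHA1
TF
HP
SERPINA1
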