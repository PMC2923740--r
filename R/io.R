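#' @name table_io
#' @title Tab-separated table readers and writers
#'
#' @description All pipeline tables are tab-separated with a header row,
#' missing values serialized as `NA`, and floats written at full
#' precision. `read_*` functions validate the column contract and error
#' with the offending line where possible; every reader/writer pair
#' round-trips (`read(write(x))` equals `x`).
#'
#' @param x Object to write.
#' @param path File path.
NULL

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path, required = NULL, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(x))
    if (length(miss))
      stop(what, " file ", path, " lacks columns: ",
           paste(miss, collapse = ", "))
  }
  x
}

#' @rdname table_io
#' @export
write_peptide_table <- function(x, path) write_tsv(x, path)

#' @rdname table_io
#' @export
read_peptide_table <- function(path) {
  x <- read_tsv(path, required = c(
    "experiment_id", "disease", "pair_index", "label_on_case",
    "protein_group_id", "peptide_id", "heavy_area", "light_area",
    "is_depleted_target", "is_defunct"), what = "peptide ratio")
  x$label_on_case <- as.logical(x$label_on_case)
  x$is_depleted_target <- as.logical(x$is_depleted_target)
  x$is_defunct <- as.logical(x$is_defunct)
  validate_peptide_table(x)
  x
}

#' @rdname table_io
#' @export
write_protein_matrix <- function(x, path) {
  stopifnot(inherits(x, "protein_ratio_matrix"))
  long <- expand.grid(protein_group_id = rownames(x$y),
                      experiment_id = colnames(x$y),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(long$experiment_id, x$pairs$experiment_id)
  long$disease <- x$pairs$disease[i]
  long$pair_index <- x$pairs$pair_index[i]
  long$x <- x$pairs$x[i]
  long$centering <- unname(x$centering[long$experiment_id])
  long$y <- x$y[cbind(long$protein_group_id, long$experiment_id)]
  long$w <- x$w[cbind(long$protein_group_id, long$experiment_id)]
  write_tsv(long, path)
}

#' @rdname table_io
#' @export
read_protein_matrix <- function(path) {
  long <- read_tsv(path, required = c(
    "protein_group_id", "experiment_id", "disease", "pair_index", "x",
    "centering", "y", "w"), what = "protein ratio matrix")
  prot <- unique(long$protein_group_id)
  exps <- unique(long$experiment_id)
  y <- matrix(NA_real_, length(prot), length(exps),
              dimnames = list(prot, exps))
  w <- y
  y[cbind(long$protein_group_id, long$experiment_id)] <- long$y
  w[cbind(long$protein_group_id, long$experiment_id)] <- long$w
  first <- !duplicated(long$experiment_id)
  pairs <- data.frame(experiment_id = long$experiment_id[first],
                      disease = long$disease[first],
                      pair_index = long$pair_index[first],
                      x = long$x[first], stringsAsFactors = FALSE)
  pairs <- pairs[match(exps, pairs$experiment_id), ]
  rownames(pairs) <- NULL
  centering <- stats::setNames(long$centering[first], long$experiment_id[first])
  structure(list(y = y, w = w, pairs = pairs, centering = centering[exps]),
            class = "protein_ratio_matrix")
}

#' @rdname table_io
#' @export
write_diff_results <- function(x, path) write_tsv(x, path)

#' @rdname table_io
#' @export
read_diff_results <- function(path) {
  read_tsv(path, required = c("protein", "disease", "log2_ratio", "p"),
           what = "differential result")
}

#' @rdname table_io
#' @export
write_elisa_pairs <- function(x, path) write_tsv(x, path)

#' @rdname table_io
#' @export
read_elisa_pairs <- function(path) {
  x <- read_tsv(path, required = c("pair_id", "case_conc", "control_conc"),
                what = "matched-pair")
  if (anyDuplicated(x$pair_id)) stop("duplicate pair ids in ", path)
  x
}

#' @rdname table_io
#' @export
write_ht_effects <- function(x, path) write_tsv(x, path)

#' @rdname table_io
#' @export
read_ht_effects <- function(path) {
  read_tsv(path, required = c("protein", "ep_log2", "ep_p",
                              "ealone_log2", "ealone_p"),
           what = "treatment-effect")
}

#' @rdname table_io
#' @export
write_set_results <- function(x, path) write_tsv(x, path)

#' Read a GMT protein-set file
#'
#' GMT format: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`; at least one member
#' per set is required.
#'
#' @param path Path to a GMT file.
#' @return Named list of character member vectors, with the descriptions
#'   as attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields (name, description, members)")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name at GMT line ", i, ": ", nm)
    sets[[nm]] <- f[-(1:2)]
    desc[nm] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT protein-set file
#'
#' @param sets Named list of character member vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the set
#'   names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm]))
      descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a plain-text protein id list (one id per line)
#'
#' @param path Path to the list file.
#' @return Character vector of ids (blank lines and `#` comments
#'   dropped).
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
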