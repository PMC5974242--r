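#' Probe-level intensity tables
#'
#' A probe table is a long-format `data.frame` with one row per
#' (probe, array) measurement and columns `transcript_cluster_id`,
#' `probe_set_id`, `probe_id`, `array_id`, `intensity`. The measurement scale
#' is carried in the attribute `scale_flag` (`"raw"` or `"log2"`).
#'
#' Invariants enforced by [validate_probe_table()]:
#' * each (probe_id, array_id) pair appears at most once;
#' * every probe_id maps to exactly one probe_set_id, and every probe_set_id
#'   to exactly one transcript_cluster_id;
#' * raw intensities are strictly positive.
#'
#' @param df data.frame with the five required columns.
#' @param scale_flag `"raw"` or `"log2"`.
#' @return A `probe_table` (data.frame subclass) with a `scale_flag`
#'   attribute.
#' @export
probe_table <- function(df, scale_flag = c("raw", "log2")) {
  scale_flag <- match.arg(scale_flag)
  req <- c("transcript_cluster_id", "probe_set_id", "probe_id",
           "array_id", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("probe table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  for (col in req[1:4]) df[[col]] <- as.character(df[[col]])
  df$intensity <- as.numeric(df$intensity)
  attr(df, "scale_flag") <- scale_flag
  class(df) <- c("probe_table", "data.frame")
  validate_probe_table(df)
}

#' @rdname probe_table
#' @param x a `probe_table`.
#' @export
probe_scale <- function(x) {
  s <- attr(x, "scale_flag")
  if (is.null(s)) "raw" else s
}

#' @rdname probe_table
#' @export
validate_probe_table <- function(x) {
  key <- paste(x$probe_id, x$array_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate measurement for probe '", d$probe_id,
         "' on array '", d$array_id, "'")
  }
  .assert_unique_map(x$probe_id, x$probe_set_id, "probe", "probe set")
  .assert_unique_map(x$probe_set_id, x$transcript_cluster_id,
                     "probe set", "transcript cluster")
  if (any(!is.finite(x$intensity))) {
    stop("non-finite intensity values present")
  }
  if (probe_scale(x) == "raw" && any(x$intensity <= 0)) {
    bad <- x[x$intensity <= 0, ][1, ]
    stop("nonpositive raw intensity for probe '", bad$probe_id,
         "' on array '", bad$array_id, "'")
  }
  x
}

.assert_unique_map <- function(from, to, from_lab, to_lab) {
  tab <- unique(data.frame(from = from, to = to))
  dup <- tab$from[duplicated(tab$from)]
  if (length(dup)) {
    stop(from_lab, " '", dup[1], "' maps to more than one ", to_lab)
  }
  invisible(TRUE)
}

#' Read / write probe tables as tab-separated text
#'
#' Reading is gzip-transparent (any connection `read.delim` accepts).
#'
#' @param path file path (optionally `.gz`).
#' @param scale_flag scale of the stored intensities.
#' @return [read_probe_table()] returns a `probe_table`;
#'   [write_probe_table()] returns `path` invisibly.
#' @export
read_probe_table <- function(path, scale_flag = c("raw", "log2")) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  df$intensity <- as.numeric(df$intensity)
  probe_table(df, match.arg(scale_flag))
}

#' @rdname read_probe_table
#' @param x a `probe_table`.
#' @export
write_probe_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' Internal TSV writer used for all result tables
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = "")
}

#' Reshape a probe table to a probes-by-arrays intensity matrix
#'
#' Errors if arrays do not share an identical probe universe, naming the
#' offending array.
#'
#' @param x a `probe_table`.
#' @return numeric matrix, rownames = probe ids, colnames = array ids.
#' @export
probe_matrix <- function(x) {
  probes <- sort(unique(x$probe_id))
  arrays <- sort(unique(x$array_id))
  counts <- table(x$array_id)
  bad <- names(counts)[counts != length(probes)]
  if (length(bad)) {
    stop("array '", bad[1], "' has ", counts[bad[1]],
         " probes; expected ", length(probes))
  }
  m <- matrix(NA_real_, length(probes), length(arrays),
              dimnames = list(probes, arrays))
  m[cbind(match(x$probe_id, probes), match(x$array_id, arrays))] <- x$intensity
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("probe '", probes[miss[1]], "' missing on array '",
         arrays[miss[2]], "'")
  }
  m
}

#' Replace intensities of a probe table from a probes-by-arrays matrix
#' @noRd
set_intensities <- function(x, m) {
  x$intensity <- m[cbind(match(x$probe_id, rownames(m)),
                         match(x$array_id, colnames(m)))]
  x
}

#' Read a sample sheet assigning arrays to two groups
#'
#' Tab-separated, columns `array_id`, `group` and optionally `pair_id`.
#'
#' @param path file path.
#' @return data.frame with character columns.
#' @export
read_groups <- function(path) {
  g <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("array_id", "group") %in% names(g))) {
    stop("groups table needs columns 'array_id' and 'group'")
  }
  g
}
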