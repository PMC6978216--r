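#' Read and write connectivity matrices as undirected edge-list TSV
#'
#' The on-disk dialect is a tab-separated file with header
#' `region_a  region_b  weight`, one row per undirected edge, endpoint
#' labels in lexicographic order; absent pairs are weight 0. Comment lines
#' starting with `#` carry metadata (units, threshold) and are ignored on
#' read. A file listing both orientations of a pair with inconsistent
#' weights is rejected.
#'
#' @param path File path.
#' @param parcellation A [parcellation] defining the node universe.
#' @param threshold Threshold recorded on the returned matrix (the file is
#'   assumed already thresholded; no weights are altered on read).
#' @return `read_edge_list()` returns a `connectivity_matrix`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path, parcellation, threshold = 0) {
  stopifnot(inherits(parcellation, "parcellation"))
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty edge-list file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!identical(header[1:3], c("region_a", "region_b", "weight")))
    stop("line ", lineno[1L],
         ": expected header 'region_a\tregion_b\tweight' in ", path)
  fields <- fields[-1L]
  lineno <- lineno[-1L]
  labels <- parcellation$labels
  n <- length(labels)
  w <- matrix(0, n, n)
  if (length(fields)) {
    nf <- lengths(fields)
    if (any(nf != 3L))
      stop("line ", lineno[which(nf != 3L)[1L]],
           ": expected 3 tab-separated fields")
    ra <- vapply(fields, `[[`, "", 1L)
    rb <- vapply(fields, `[[`, "", 2L)
    wt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(wt))
      stop("line ", lineno[which(is.na(wt))[1L]], ": non-numeric weight")
    ia <- match(ra, labels)
    ib <- match(rb, labels)
    if (anyNA(ia) || anyNA(ib)) {
      bad <- which(is.na(ia) | is.na(ib))[1L]
      stop("line ", lineno[bad], ": unknown region label(s): ",
           paste(setdiff(c(ra[bad], rb[bad]), labels), collapse = ", "))
    }
    if (any(ia == ib))
      stop("line ", lineno[which(ia == ib)[1L]], ": self-loop edge")
    i <- pmin(ia, ib)
    j <- pmax(ia, ib)
    key <- (i - 1L) * n + j
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      rng <- tapply(wt[dup], key[dup], function(v) diff(range(v)))
      if (any(rng > 0)) {
        badkey <- as.integer(names(rng)[rng > 0][1L])
        bad <- which(key == badkey)
        stop("inconsistent duplicate edge (",
             labels[i[bad[1L]]], ", ", labels[j[bad[1L]]],
             ") at lines ", paste(lineno[bad], collapse = ", "))
      }
    }
    w[cbind(i, j)] <- wt
    w[cbind(j, i)] <- wt
  }
  new_connectivity_matrix(w, parcellation, threshold)
}

#' @rdname read_edge_list
#' @param matrix A `connectivity_matrix`.
#' @export
write_edge_list <- function(matrix, path) {
  validate_connectivity_matrix(matrix)
  w <- matrix$weights
  labels <- matrix$parcellation$labels
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  a <- labels[ut[, 1L]]
  b <- labels[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# undirected structural connectome edge list",
    "# weight units: 1/mm (scaled inverse streamline length sums)",
    sprintf("# threshold_applied: %.17g", matrix$threshold),
    "region_a\tregion_b\tweight"), con)
  if (nrow(ut))
    writeLines(sprintf("%s\t%s\t%.17g",
                       a[ord], b[ord], w[ut][ord]), con)
  invisible(path)
}

#' Read and write streamline records as TSV
#'
#' Format: comment header lines carrying `subject`, `wave` and `scale`,
#' then a header row `region_a  region_b  length_mm` and one row per
#' streamline.
#'
#' @param path File path.
#' @param parcellation Optional [parcellation] for label validation.
#' @return `read_streamlines()` returns a [streamline_set];
#'   `write_streamlines()` returns `path` invisibly.
#' @export
read_streamlines <- function(path, parcellation = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
  }
  scale <- as.numeric(get_meta("scale", "1"))
  subject <- get_meta("subject", "S1")
  wave <- get_meta("wave", "baseline")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body) ||
      !identical(strsplit(body[1L], "\t")[[1L]][1:3],
                 c("region_a", "region_b", "length_mm")))
    stop("expected header 'region_a\tregion_b\tlength_mm' in ", path)
  df <- if (length(body) > 1L) {
    parts <- strsplit(body[-1L], "\t", fixed = TRUE)
    data.frame(region_a = vapply(parts, `[[`, "", 1L),
               region_b = vapply(parts, `[[`, "", 2L),
               length = as.numeric(vapply(parts, `[[`, "", 3L)))
  } else {
    data.frame(region_a = character(), region_b = character(),
               length = numeric())
  }
  streamline_set(df, scale = scale, subject_id = subject, wave = wave,
                 parcellation = parcellation)
}

#' @rdname read_streamlines
#' @param streamlines A [streamline_set].
#' @export
write_streamlines <- function(streamlines, path) {
  stopifnot(inherits(streamlines, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject: %s", streamlines$subject_id),
    sprintf("# wave: %s", streamlines$wave),
    sprintf("# scale: %.17g", streamlines$scale),
    "region_a\tregion_b\tlength_mm"), con)
  r <- streamlines$records
  if (nrow(r))
    writeLines(sprintf("%s\t%s\t%.17g", r$region_a, r$region_b, r$length),
               con)
  invisible(path)
}
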