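#' Create a set of streamline records for one subject and wave
#'
#' A streamline set holds the raw tractography evidence for one structural
#' connectome: one record per reconstructed streamline, giving the pair of
#' endpoint regions and the streamline length in millimetres, plus a
#' subject-level seed-density scale factor that corrects connection
#' strengths for the number of tractography seeds per unit area.
#'
#' @param records Data frame with columns `region_a`, `region_b`
#'   (character region labels) and `length` (streamline length, mm, > 0).
#' @param scale Positive scalar seed-density correction factor applied
#'   multiplicatively to all connection weights of this subject.
#' @param subject_id,wave Identifiers; `wave` must be `"baseline"` or
#'   `"followup"`.
#' @param parcellation Optional [parcellation]; when given, region labels
#'   are validated immediately.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(records, scale = 1, subject_id = "S1",
                           wave = c("baseline", "followup"),
                           parcellation = NULL) {
  wave <- match.arg(wave)
  records <- as.data.frame(records)
  need <- c("region_a", "region_b", "length")
  if (!all(need %in% names(records)))
    stop("`records` must have columns region_a, region_b, length")
  records <- records[need]
  if (nrow(records)) {
    bad_len <- which(!is.finite(records$length) | records$length <= 0)
    if (length(bad_len))
      stop("streamline length must be strictly positive; bad record(s): ",
           paste(utils::head(bad_len, 5), collapse = ", "))
    loops <- which(records$region_a == records$region_b)
    if (length(loops))
      stop("self-loop streamline records are not allowed; record(s): ",
           paste(utils::head(loops, 5), collapse = ", "))
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("`scale` must be a positive scalar")
  if (!is.null(parcellation)) {
    unknown <- setdiff(unique(c(records$region_a, records$region_b)),
                       parcellation$labels)
    if (length(unknown))
      stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(records = records, scale = scale,
                 subject_id = subject_id, wave = wave),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("Streamline set:", nrow(x$records), "records, subject",
      x$subject_id, "(", x$wave, "), scale =", x$scale, "\n")
  invisible(x)
}

new_connectivity_matrix <- function(weights, parcellation, threshold) {
  dimnames(weights) <- list(parcellation$labels, parcellation$labels)
  structure(list(weights = weights, parcellation = parcellation,
                 threshold = threshold),
            class = "connectivity_matrix")
}

#' Build a weighted structural connectivity matrix from streamlines
#'
#' The weight of the connection between two regions is the scaled sum of
#' inverse streamline lengths over all streamlines terminating in that
#' region pair: `w(i, j) = scale * sum(1 / length)`. Summing inverse
#' lengths, rather than counting streamlines, corrects the linear bias of
#' deterministic tractography towards long fibres; the subject-level
#' `scale` corrects for the seeding scheme. Weights below `threshold`
#' (default 1) are set to zero to suppress noise-driven spurious
#' connections.
#'
#' @param streamlines A [streamline_set].
#' @param parcellation A [parcellation] defining the node universe.
#' @param threshold Non-negative scalar; weights strictly below it are
#'   zeroed. The paper-style default is 1.
#' @return A `connectivity_matrix`: symmetric non-negative weights with a
#'   zero diagonal, in units of 1/mm (scaled), plus the parcellation and
#'   the threshold that was applied.
#' @examples
#' p <- parcellation(c("A", "B", "C"))
#' s <- streamline_set(data.frame(region_a = c("A", "A"),
#'                                region_b = c("B", "B"),
#'                                length = c(2, 4)))
#' m <- build_connectivity_matrix(s, p, threshold = 0)
#' m$weights["A", "B"]  # 1/2 + 1/4 = 0.75
#' @export
build_connectivity_matrix <- function(streamlines, parcellation,
                                      threshold = 1) {
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(parcellation, "parcellation"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("`threshold` must be a non-negative scalar")
  labels <- parcellation$labels
  n <- length(labels)
  w <- matrix(0, n, n)
  rec <- streamlines$records
  if (nrow(rec)) {
    ia <- match(rec$region_a, labels)
    ib <- match(rec$region_b, labels)
    if (anyNA(ia) || anyNA(ib)) {
      unknown <- unique(c(rec$region_a[is.na(ia)], rec$region_b[is.na(ib)]))
      stop("unknown region label(s): ", paste(unknown, collapse = ", "))
    }
    i <- pmin(ia, ib)
    j <- pmax(ia, ib)
    contrib <- streamlines$scale / rec$length
    agg <- rowsum(contrib, group = (i - 1L) * n + j)
    key <- as.integer(rownames(agg))
    ii <- (key - 1L) %/% n + 1L
    jj <- (key - 1L) %% n + 1L
    w[cbind(ii, jj)] <- agg[, 1L]
    w[cbind(jj, ii)] <- agg[, 1L]
  }
  w[w < threshold] <- 0
  new_connectivity_matrix(w, parcellation, threshold)
}

#' Apply (or raise) the noise threshold of a connectivity matrix
#'
#' @param matrix A `connectivity_matrix`.
#' @param threshold Non-negative scalar; weights strictly below it become 0.
#' @return The thresholded `connectivity_matrix`.
#' @export
apply_threshold <- function(matrix, threshold) {
  stopifnot(inherits(matrix, "connectivity_matrix"), threshold >= 0)
  w <- matrix$weights
  w[w < threshold] <- 0
  new_connectivity_matrix(w, matrix$parcellation,
                          max(threshold, matrix$threshold))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Connectivity matrix:", n, "regions,", ne, "edges",
      sprintf("(density %.3f), threshold %g\n",
              ne / (n * (n - 1) / 2), x$threshold))
  invisible(x)
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$weights

validate_connectivity_matrix <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  w <- m$weights
  if (!isTRUE(all.equal(w, t(w))))
    stop("connectivity matrix is not symmetric")
  if (any(diag(w) != 0)) stop("connectivity matrix diagonal must be zero")
  if (any(w < 0)) stop("connectivity weights must be non-negative")
  invisible(m)
}
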