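#' Classify connections as rich-club, feeder or peripheral
#'
#' Given a fixed a-priori rich-club node set, every present connection of
#' the network falls in exactly one class: connections between two
#' rich-club regions are *rich-club* connections, connections with exactly
#' one rich-club endpoint are *feeder* connections, and connections between
#' non-rich-club regions are *peripheral* connections.
#'
#' @param matrix A `connectivity_matrix`.
#' @param parcellation A [parcellation] supplying the rich-club set;
#'   defaults to the matrix's own parcellation.
#' @return An object of class `richclub_partition`: a list with `edges`
#'   (data frame: `region_a`, `region_b`, `weight`, `class`), `counts`
#'   (named integer vector over the three classes) and the parcellation.
#' @export
classify_edges <- function(matrix, parcellation = matrix$parcellation) {
  validate_connectivity_matrix(matrix)
  stopifnot(inherits(parcellation, "parcellation"))
  if (!identical(parcellation$labels, matrix$parcellation$labels))
    stop("parcellation labels do not match the matrix")
  if (!length(parcellation$rich_club))
    warning("rich-club set is empty: all connections are peripheral")
  w <- matrix$weights
  labels <- parcellation$labels
  is_rich <- labels %in% parcellation$rich_club
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  n_rich_ends <- is_rich[ut[, 1L]] + is_rich[ut[, 2L]]
  cls <- factor(c("peripheral", "feeder", "rich_club")[n_rich_ends + 1L],
                levels = c("rich_club", "feeder", "peripheral"))
  edges <- data.frame(region_a = labels[ut[, 1L]],
                      region_b = labels[ut[, 2L]],
                      weight = w[ut], class = cls,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, counts = table(cls),
                 parcellation = parcellation),
            class = "richclub_partition")
}

#' @export
print.richclub_partition <- function(x, ...) {
  cat("Connection classes:", sum(x$counts), "edges\n")
  print(x$counts)
  invisible(x)
}

#' Mean connection strength per connection class
#'
#' The strength of each connection class is the average edge weight over
#' the *present* edges of that class; a class with no present edges has a
#' missing (`NA`) strength, never 0.
#'
#' @param partition A `richclub_partition` from [classify_edges()].
#' @return Named numeric vector `c(rich_club=, feeder=, peripheral=)`.
#' @export
class_mean_strength <- function(partition) {
  stopifnot(inherits(partition, "richclub_partition"))
  out <- c(rich_club = NA_real_, feeder = NA_real_, peripheral = NA_real_)
  if (nrow(partition$edges)) {
    m <- tapply(partition$edges$weight, partition$edges$class, mean)
    out[names(m)] <- m
  }
  out
}

#' Degree ranks of the rich-club regions
#'
#' Reports, for each rich-club region, its degree and dense degree rank
#' (tied degrees share a rank) and whether it falls within the top-`k`
#' degree ranks of the network — the empirical check that the a-priori hub
#' set is indeed among the most connected regions of the study population.
#'
#' @param matrix A `connectivity_matrix`.
#' @param parcellation A [parcellation]; defaults to the matrix's own.
#' @param k Positive integer rank cut-off (at most the number of regions).
#' @return A data frame (`label`, `degree`, `rank`, `in_top_k`) with one
#'   row per rich-club region and an attribute `all_in_top_k`.
#' @export
degree_rank_report <- function(matrix, parcellation = matrix$parcellation,
                               k = 12L) {
  stopifnot(inherits(parcellation, "parcellation"))
  deg <- node_degree(matrix)
  if (k < 1L || k > length(deg)) stop("`k` must be in 1..n_regions")
  uniq <- sort(unique(deg), decreasing = TRUE)
  rank <- match(deg, uniq)  # dense rank: ties share a rank
  rich <- parcellation$rich_club
  idx <- match(rich, parcellation$labels)
  out <- data.frame(label = rich, degree = deg[idx], rank = rank[idx],
                    in_top_k = rank[idx] <= k, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "all_in_top_k") <- all(out$in_top_k)
  out
}

#' Full metric profile of one connectome
#'
#' Convenience wrapper returning every network measure used by the
#' longitudinal analyses in one row: density, total strength, global
#' efficiency, and the rich-club / feeder / peripheral class strengths and
#' edge counts.
#'
#' @param matrix A `connectivity_matrix`.
#' @param parcellation A [parcellation]; defaults to the matrix's own.
#' @return A one-row data frame.
#' @export
network_metric_profile <- function(matrix,
                                   parcellation = matrix$parcellation) {
  part <- classify_edges(matrix, parcellation)
  cs <- class_mean_strength(part)
  data.frame(density = network_density(matrix),
             total_strength = total_network_strength(matrix),
             global_efficiency = global_efficiency(matrix),
             rich_club_strength = cs[["rich_club"]],
             feeder_strength = cs[["feeder"]],
             peripheral_strength = cs[["peripheral"]],
             rich_club_edges = as.integer(part$counts[["rich_club"]]),
             feeder_edges = as.integer(part$counts[["feeder"]]),
             peripheral_edges = as.integer(part$counts[["peripheral"]]))
}
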