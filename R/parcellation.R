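#' Define a brain parcellation with a fixed rich-club node set
#'
#' A parcellation is the ordered set of grey-matter regions over which all
#' connectivity matrices are defined, together with an a-priori subset of
#' rich-club regions: hub regions that are both highly connected to the rest
#' of the network and densely interconnected with each other.
#'
#' @param labels Character vector of unique region names; their order fixes
#'   the row/column order of every connectivity matrix.
#' @param rich_club Character vector, a subset of `labels`, naming the
#'   rich-club regions. May be empty.
#' @return An object of class `parcellation`: a list with elements `labels`
#'   and `rich_club`.
#' @seealso [aal90_parcellation()] for the default 90-region cortical and
#'   subcortical parcellation.
#' @export
parcellation <- function(labels, rich_club = character()) {
  if (!is.character(labels) || length(labels) < 2L)
    stop("`labels` must be a character vector with at least 2 regions")
  if (anyDuplicated(labels))
    stop("region labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rich_club <- as.character(rich_club)
  missing <- setdiff(rich_club, labels)
  if (length(missing))
    stop("rich-club labels not in parcellation: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, rich_club = rich_club),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation:", length(x$labels), "regions,",
      length(x$rich_club), "rich-club regions\n")
  if (length(x$rich_club))
    cat("  rich club:", paste(x$rich_club, collapse = ", "), "\n")
  invisible(x)
}

#' The 90-region AAL parcellation with its canonical rich club
#'
#' Returns the 90 cortical and subcortical regions of the Automated
#' Anatomical Labelling atlas (cerebellum excluded), in the standard
#' left/right interleaved order. The rich club is fixed a priori as the
#' bilateral superior frontal gyrus, precuneus, superior parietal gyrus and
#' insula (8 regions), the hub set repeatedly identified in structural
#' connectome studies of ageing and small vessel disease.
#'
#' @return A [parcellation] with 90 labels and 8 rich-club labels.
#' @export
aal90_parcellation <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  labels <- as.vector(t(outer(base, c("_L", "_R"), paste0)))
  rich <- as.vector(t(outer(
    c("Frontal_Sup", "Precuneus", "Parietal_Sup", "Insula"),
    c("_L", "_R"), paste0)))
  parcellation(labels, rich)
}

#' Read or write a parcellation as a two-column CSV
#'
#' The on-disk format is a CSV with columns `label` and `rich_club`
#' (0/1), one row per region in matrix order.
#'
#' @param path File path.
#' @return `read_parcellation()` returns a [parcellation];
#'   `write_parcellation()` returns `path` invisibly.
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "rich_club") %in% names(df)))
    stop("parcellation file must have columns `label` and `rich_club`: ", path)
  parcellation(df$label, df$label[df$rich_club != 0])
}

#' @rdname read_parcellation
#' @param parc A [parcellation].
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  df <- data.frame(label = parc$labels,
                   rich_club = as.integer(parc$labels %in% parc$rich_club))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
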