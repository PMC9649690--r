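#' Join regulatory edges and drug associations into RBP-transcript-drug axes
#'
#' An axis exists for every (RBP, transcript) regulatory edge whose
#' transcript also appears in a called (transcript, drug) association: the
#' join is an exact relational join on transcript id, so a transcript
#' regulated by `r` RBPs and associated with `d` drugs contributes
#' `r * d` axes.
#'
#' @param edges data.frame from [build_network()] (`rbp_id`,
#'   `transcript_id`, `direction`, ...).
#' @param associations data.frame of called associations
#'   (`transcript_id`, `drug_id`, `score`, `direction`, ...).
#' @return data.frame of axes: `rbp_id`, `transcript_id`, `drug_id`,
#'   `regulation_direction`, `association_direction`, `score`.
#' @export
build_axes <- function(edges, associations) {
  e <- data.frame(rbp_id = edges$rbp_id, transcript_id = edges$transcript_id,
                  regulation_direction = edges$direction,
                  stringsAsFactors = FALSE)
  a <- data.frame(transcript_id = associations$transcript_id,
                  drug_id = associations$drug_id,
                  association_direction = associations$direction,
                  score = associations$score,
                  stringsAsFactors = FALSE)
  if (nrow(e) && nrow(a) &&
      !length(intersect(e$transcript_id, a$transcript_id)))
    warning("no shared transcript ids between edges and associations",
            call. = FALSE)
  axes <- merge(e, a, by = "transcript_id")
  axes <- axes[order(axes$rbp_id, axes$transcript_id, axes$drug_id),
               c("rbp_id", "transcript_id", "drug_id",
                 "regulation_direction", "association_direction", "score")]
  rownames(axes) <- NULL
  axes
}

#' Summarize an axis set
#'
#' Reports the distinct RBPs, bridging transcripts, and drugs, the fraction
#' of bridging transcripts that are unannotated, and the fraction of
#' distinct (RBP, drug) connections supported only by unannotated
#' transcripts.
#'
#' @param axes data.frame from [build_axes()].
#' @param annotation_of named character vector mapping transcript id to
#'   `"annotated"` or `"unannotated"`; transcripts missing from the map are
#'   treated as annotated.
#' @return List: `n_axes`, `n_rbps`, `n_transcripts`, `n_drugs`,
#'   `frac_bridging_unannotated`, `n_rbp_drug_connections`,
#'   `frac_connections_only_unannotated`.
#' @export
summarize_axes <- function(axes, annotation_of = character(0)) {
  tx <- unique(axes$transcript_id)
  unann <- stats::setNames(
    unname(annotation_of[tx]) == "unannotated", tx)
  unann[is.na(unann)] <- FALSE
  conn <- paste(axes$rbp_id, axes$drug_id, sep = "\r")
  conn_only_unann <- tapply(unann[axes$transcript_id], conn, all)
  list(
    n_axes = nrow(axes),
    n_rbps = length(unique(axes$rbp_id)),
    n_transcripts = length(tx),
    n_drugs = length(unique(axes$drug_id)),
    frac_bridging_unannotated = if (length(tx)) mean(unann) else NA_real_,
    n_rbp_drug_connections = length(unique(conn)),
    frac_connections_only_unannotated =
      if (length(conn)) mean(conn_only_unann) else NA_real_)
}

#' Export axes as Sankey-ready node/link lists
#'
#' @param axes data.frame from [build_axes()].
#' @return List with `nodes` (data.frame `id`, `type`) and `links`
#'   (data.frame `source`, `target`, `value`).
#' @export
axes_to_sankey <- function(axes) {
  nodes <- rbind(
    data.frame(id = unique(axes$rbp_id), type = "rbp"),
    data.frame(id = unique(axes$transcript_id), type = "transcript"),
    data.frame(id = unique(axes$drug_id), type = "drug"))
  rt <- stats::aggregate(list(value = axes$drug_id),
                         by = list(source = axes$rbp_id,
                                   target = axes$transcript_id),
                         FUN = length)
  td <- stats::aggregate(list(value = axes$rbp_id),
                         by = list(source = axes$transcript_id,
                                   target = axes$drug_id),
                         FUN = length)
  list(nodes = nodes, links = rbind(rt, td))
}
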