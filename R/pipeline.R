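# End-to-end classification: hits -> cleaned pair scores -> thresholded
# network -> greedy modularity communities -> size filter -> subfamily
# labels and centroids.

#' Classify TE copies into subfamilies from an all-vs-all hit table
#'
#' Runs the whole consensus-free classification: cleans the hits
#' ([remove_self_and_reciprocal()]), merges HSPs into per-pair identity and
#' coverage ([score_pairs()]), builds the thresholded similarity network
#' ([build_network()]), detects unweighted greedy modularity communities
#' ([greedy_modularity_communities()]), drops small communities
#' ([filter_small_communities()]) and assigns subfamily labels
#' ([assign_labels()]), with one centroid exemplar per kept community.
#'
#' @param hits Hits data.frame (canonical form, e.g. from
#'   [read_tabular_hits()] or [truth_hits()]).
#' @param lengths Named integer vector of sequence lengths (every id to
#'   classify must be present; ids without hits become isolated nodes).
#' @param min_identity,min_coverage Network thresholds (defaults 80/80; use
#'   70 coverage for internal-region networks).
#' @param min_community Minimum community size (default 5).
#' @param keep_rule Community-size rule, `"ge"` or `"gt"`; see
#'   [filter_small_communities()].
#' @param merge_map Optional merge rules for [assign_labels()].
#' @param prefix Subfamily label prefix (default `"LTR"`).
#' @param coverage_ref Coverage denominator passed to [score_pairs()].
#' @param strict Strict (`>`) thresholds, the default.
#' @return A list of class `ssn_classification`: `classification`
#'   (data.frame `id, label, community, degree, is_centroid`), `network`
#'   (`ssn`), `partition` (full `ssn_partition`), `kept`, `unclassified`,
#'   `centroids` (named by community label), `pairs` (pair scores).
#' @export
classify_copies <- function(hits, lengths, min_identity = 80,
                            min_coverage = 80, min_community = 5,
                            keep_rule = c("ge", "gt"), merge_map = NULL,
                            prefix = "LTR",
                            coverage_ref = c("query", "shorter", "longer"),
                            strict = TRUE) {
  keep_rule <- match.arg(keep_rule)
  coverage_ref <- match.arg(coverage_ref)
  cleaned <- remove_self_and_reciprocal(hits)
  pairs <- score_pairs(cleaned, lengths, coverage_ref = coverage_ref)
  net <- build_network(pairs, nodes = names(lengths),
                       min_identity = min_identity,
                       min_coverage = min_coverage, strict = strict)
  part <- greedy_modularity_communities(net)
  filt <- filter_small_communities(part, min_size = min_community,
                                   keep_rule = keep_rule)
  labels <- assign_labels(filt$kept, merge_map = merge_map, prefix = prefix,
                          unclassified = filt$unclassified)
  cents <- vapply(filt$kept$communities, function(comm) centroid(net, comm),
                  character(1L))
  names(cents) <- filt$kept$labels
  deg <- ssn_degree(net)
  labels$degree <- as.integer(deg[labels$id])
  labels$is_centroid <- labels$id %in% cents
  structure(list(classification = labels, network = net, partition = part,
                 kept = filt$kept, unclassified = filt$unclassified,
                 centroids = cents, pairs = pairs),
            class = "ssn_classification")
}

#' @export
print.ssn_classification <- function(x, ...) {
  n_cls <- sum(x$classification$label != "Unclassified")
  cat("SSN classification: ", n_cls, " of ", nrow(x$classification),
      " copies in ", length(x$kept$communities), " kept communities (",
      length(x$unclassified), " unclassified)\n", sep = "")
  tab <- table(x$classification$label)
  tab <- tab[order(names(tab) == "Unclassified", -tab)]
  for (nm in names(tab)) {
    cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
  invisible(x)
}
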