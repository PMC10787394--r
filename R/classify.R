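# From communities to named subfamilies, plus comparison of two
# classifications of the same copies and detection of "rogue" copies that
# fall outside their subfamily's main clade in a phylogeny.

UNCLASSIFIED <- "Unclassified"

#' Turn filtered communities into named subfamily labels
#'
#' Communities listed together in a merge rule share one subfamily label
#' (nested communities are merged this way after centroid alignment, e.g.
#' two tightly nested community pairs becoming joint subfamilies). The
#' remaining communities are named `prefix` plus a rank: final groups are
#' ordered by decreasing total size, merge-rule names are honoured, and
#' unnamed groups take the smallest unused rank. Members of `unclassified`
#' (e.g. dropped small communities) get the reserved label `"Unclassified"`.
#'
#' @param partition An `ssn_partition` (already filtered by community size)
#'   or list of communities named by their community labels.
#' @param merge_map Optional list of merge rules, each a list with elements
#'   `communities` (character vector of community labels) and `name` (the
#'   subfamily label). A community may appear in at most one rule.
#' @param prefix Label prefix for unmerged communities (default `"LTR"`).
#' @param unclassified Character vector of ids to label `"Unclassified"`.
#' @return A data.frame with columns `id`, `label`, `community` (the source
#'   community label, `NA` for unclassified ids).
#' @export
assign_labels <- function(partition, merge_map = NULL, prefix = "LTR",
                          unclassified = character(0)) {
  comms <- if (inherits(partition, "ssn_partition")) {
    setNames(partition$communities, partition$labels)
  } else {
    if (is.null(names(partition))) {
      setNames(partition, as.character(seq_along(partition)))
    } else partition
  }
  if (!is.null(merge_map)) {
    all_named <- unlist(lapply(merge_map, `[[`, "communities"))
    if (anyDuplicated(all_named)) {
      stop("community appears in more than one merge rule: ",
           paste(unique(all_named[duplicated(all_named)]), collapse = ", "))
    }
    unknown <- setdiff(all_named, names(comms))
    if (length(unknown) > 0L) {
      stop("merge rule names unknown community: ",
           paste(unknown, collapse = ", "))
    }
  }
  # final groups: merged unions plus untouched communities
  groups <- list()
  named_comms <- character(0)
  for (rule in merge_map) {
    ids <- sort(unlist(comms[rule$communities], use.names = FALSE))
    groups[[length(groups) + 1L]] <- list(
      ids = ids, name = rule$name,
      community = paste(sort(rule$communities), collapse = "+"))
    named_comms <- c(named_comms, rule$communities)
  }
  for (lab in setdiff(names(comms), named_comms)) {
    groups[[length(groups) + 1L]] <- list(ids = sort(comms[[lab]]),
                                          name = NA_character_,
                                          community = lab)
  }
  ord <- order(-vapply(groups, function(g) length(g$ids), integer(1L)),
               vapply(groups, function(g) g$community, character(1L)))
  groups <- groups[ord]
  used <- vapply(groups, function(g) g$name, character(1L))
  used <- used[!is.na(used)]
  next_rank <- 1L
  for (i in seq_along(groups)) {
    if (is.na(groups[[i]]$name)) {
      repeat {
        cand <- paste0(prefix, next_rank)
        next_rank <- next_rank + 1L
        if (!cand %in% used) break
      }
      groups[[i]]$name <- cand
      used <- c(used, cand)
    }
  }
  rows <- lapply(groups, function(g) {
    data.frame(id = g$ids, label = g$name, community = g$community,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    if (length(unclassified) > 0L)
      data.frame(id = sort(as.character(unclassified)), label = UNCLASSIFIED,
                 community = NA_character_, stringsAsFactors = FALSE)
  )))
  rownames(out) <- NULL
  out
}

#' Compare two classifications of the same copies
#'
#' The comparison is restricted to ids classified (non-Unclassified) in `a`.
#' An id whose labels differ counts as a disagreement; ids absent from `b`
#' also count as disagreements and are reported separately. The rate is
#' 100 * n_disagree / n_compared.
#'
#' @param a,b Classification data.frames (columns `id`, `label`) or named
#'   character vectors of labels.
#' @return An object of class `disagreement_report`: list with `n_compared`,
#'   `n_disagree`, `n_missing_in_b`, `rate` (percent) and `confusion` (a
#'   table of label pairs over the compared ids present in both).
#' @export
compare_classifications <- function(a, b) {
  a <- as_label_vector(a)
  b <- as_label_vector(b)
  ids <- names(a)[a != UNCLASSIFIED]
  if (length(ids) == 0L) {
    warning("no classified ids to compare; rate undefined")
    return(structure(list(n_compared = 0L, n_disagree = 0L,
                          n_missing_in_b = 0L, rate = NA_real_,
                          confusion = table(character(0), character(0))),
                     class = "disagreement_report"))
  }
  in_b <- ids %in% names(b)
  n_missing <- sum(!in_b)
  both <- ids[in_b]
  differs <- a[both] != b[both]
  n_disagree <- sum(differs) + n_missing
  structure(list(
    n_compared = length(ids),
    n_disagree = as.integer(n_disagree),
    n_missing_in_b = as.integer(n_missing),
    rate = 100 * n_disagree / length(ids),
    confusion = table(a = a[both], b = b[both])
  ), class = "disagreement_report")
}

as_label_vector <- function(x) {
  if (is.data.frame(x)) {
    setNames(as.character(x$label), x$id)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
}

#' @export
print.disagreement_report <- function(x, ...) {
  cat("Classification comparison: ", x$n_disagree, " of ", x$n_compared,
      " classified copies differ (", format(round(x$rate, 2), nsmall = 2),
      "%); ", x$n_missing_in_b, " missing from the second classification\n",
      sep = "")
  invisible(x)
}

#' Detect rogue copies against a phylogeny
#'
#' For each subfamily the main clade is the internal node (the root
#' included) that maximizes the number of subfamily members among its
#' leaves, restricted to clades in which subfamily members form a strict
#' majority (a fraction greater than `purity`) of the classified leaves;
#' ties prefer the larger clade, then the one closer to the root. Rogues are
#' the subfamily members outside the main clade. If no clade clears the
#' purity threshold, all members of the subfamily are reported rogue.
#' Unclassified ids are ignored. The threshold is strict: at exactly 50-50
#' a clade does not qualify, so the main clade of a subfamily cannot be an
#' ancestor in which the subfamily is not the majority.
#'
#' @param tree A rooted `phylo` object whose tips include every classified
#'   id.
#' @param classification Classification data.frame or named label vector.
#' @param purity Purity threshold: a clade qualifies when the subfamily's
#'   fraction of its classified leaves exceeds this value (default 0.5,
#'   i.e. strict majority).
#' @return A named list mapping subfamily label to a character vector of
#'   rogue ids (possibly empty).
#' @export
detect_rogues <- function(tree, classification, purity = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  labels <- as_label_vector(classification)
  labels <- labels[labels != UNCLASSIFIED]
  missing <- setdiff(names(labels), tree$tip.label)
  if (length(missing) > 0L) {
    stop("classified id missing from tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  # leaf sets of every internal node; prop.part lists them in node order
  parts <- ape::prop.part(tree)
  clade_leaves <- lapply(parts, function(idx) tree$tip.label[idx])
  # depth of each internal node (edges from the root)
  root <- ntip + 1L
  depth <- rep(NA_integer_, ntip + tree$Nnode)
  depth[root] <- 0L
  repeat {
    updated <- FALSE
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + 1L
        updated <- TRUE
      }
    }
    if (!updated) break
  }
  clade_nodes <- ntip + seq_len(tree$Nnode)
  clade_depth <- depth[clade_nodes]
  classified_tips <- names(labels)
  out <- list()
  for (S in sort(unique(labels))) {
    members <- names(labels)[labels == S]
    n_members <- vapply(clade_leaves,
                        function(lv) sum(lv %in% members), integer(1L))
    n_classified <- vapply(clade_leaves,
                           function(lv) sum(lv %in% classified_tips),
                           integer(1L))
    qualifies <- n_classified > 0L & n_members / n_classified > purity
    if (!any(qualifies)) {
      out[[S]] <- sort(members)
      next
    }
    size <- lengths(clade_leaves)
    idx <- which(qualifies)
    ord <- order(-n_members[idx], -size[idx], clade_depth[idx])
    main <- clade_leaves[[idx[ord[1L]]]]
    out[[S]] <- sort(setdiff(members, main))
  }
  out
}

#' Read a merge-map config file
#'
#' One rule per line: `1.1,1.2 -> LTR1`. Blank lines and `#` comments are
#' ignored.
#'
#' @param path Path to the config file.
#' @return A list of merge rules suitable for [assign_labels()].
#' @export
read_merge_map <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "->", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed merge rule: ", ln)
    list(communities = trimws(strsplit(parts[1L], ",")[[1L]]),
         name = trimws(parts[2L]))
  })
}

#' Write a classification table as TSV
#'
#' @param classification Data.frame from [assign_labels()], optionally with
#'   extra columns (degree, centroid flag).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  write.table(classification, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
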