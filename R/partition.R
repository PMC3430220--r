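#' Partitions of the descriptor set
#'
#' A partition is a list of non-overlapping, non-empty character vectors
#' jointly covering a set of names. Equality between partitions is
#' label-invariant: only the grouping matters, not which neuron index (or
#' list position) a group happens to carry.
#'
#' @param groups List of character vectors.
#' @param universe Names the partition must cover exactly (default: the
#'   union of `groups`).
#' @return The canonicalized partition (groups sorted internally and by
#'   first member), class `descriptor_partition`.
#' @export
as_partition <- function(groups, universe = NULL) {
  stopifnot(is.list(groups), length(groups) > 0)
  groups <- lapply(groups, function(g) sort(as.character(g)))
  if (any(lengths(groups) == 0)) stop("partition groups must be non-empty")
  members <- unlist(groups)
  if (anyDuplicated(members))
    stop("partition groups overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  if (!is.null(universe) && !setequal(members, universe))
    stop("partition does not cover the expected name set")
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  structure(groups, class = "descriptor_partition")
}

#' Turn winning-neuron labels into a partition
#'
#' Names sharing a winning neuron form one group.
#'
#' @param labels Integer vector of neuron indices.
#' @param names Character names parallel to `labels` (defaults to
#'   `names(labels)`).
#' @return A [as_partition()] object.
#' @export
labels_to_partition <- function(labels, names = base::names(labels)) {
  stopifnot(length(labels) == length(names), !is.null(names))
  as_partition(unname(split(names, labels)))
}

#' Canonical string signature of a partition
#'
#' Identical signatures iff the partitions are equal up to relabeling.
#'
#' @param partition A partition (list of character groups).
#' @return A single string.
#' @export
partition_signature <- function(partition) {
  paste(sort(vapply(partition, function(g) paste(sort(g), collapse = "+"), "")),
        collapse = " | ")
}

#' Label-invariant partition equality
#'
#' @param a,b Partitions (lists of character groups).
#' @return Logical.
#' @export
partitions_equal <- function(a, b) {
  identical(partition_signature(a), partition_signature(b))
}

#' @export
print.descriptor_partition <- function(x, ...) {
  cat("Partition with", length(x), "group(s):\n")
  for (g in x) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}
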