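#' Tally regulation instances across a group's sample networks
#'
#' Counts how many sample-specific networks contain each distinct
#' regulation instance. The denominator for frequencies is the total number
#' of samples in the group, including samples whose network is empty.
#'
#' @param nets a `dera_sample_networks` list (or plain list of instance
#'   data frames), one element per sample.
#' @return data frame with the instance columns plus `count` and
#'   `frequency` (`count / group_size`), rows sorted; attribute
#'   `group_size`; class `dera_freq`.
#' @export
frequency_table <- function(nets) {
  if (length(nets) == 0L) stop("no sample networks given")
  all_inst <- do.call(rbind, lapply(unclass(nets), function(x)
    x[, INSTANCE_COLS, drop = FALSE]))
  group_size <- length(nets)
  if (is.null(all_inst) || nrow(all_inst) == 0L) {
    out <- cbind(.empty_instances(), count = integer(0),
                 frequency = numeric(0))
  } else {
    key <- paste(all_inst$source, all_inst$effect, all_inst$target,
                 all_inst$source_state, sep = "\r")
    first <- !duplicated(key)
    out <- all_inst[first, , drop = FALSE]
    out$count <- as.integer(table(key)[key[first]])
    out$frequency <- out$count / group_size
    out <- out[order(out$source, out$target, out$effect, out$source_state), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "group_size") <- group_size
  class(out) <- c("dera_freq", "data.frame")
  out
}

#' Identify core regulations at threshold T
#'
#' A core regulation is a regulation instance present identically (same
#' edge, same sign pattern) in at least a fraction `T` of the group's
#' samples. The comparison is inclusive (`frequency >= T`). The
#' conventional discovery threshold is `T = 0.5`; small or heterogeneous
#' validation cohorts are often assessed at a slightly lower `T = 0.4`.
#'
#' @param freq a `dera_freq` table from [frequency_table()].
#' @param T prevalence threshold in (0, 1].
#' @param group_label optional phenotype label recorded on the result.
#' @return class `dera_core`: a data frame of instances with `count`,
#'   `frequency`, and a `component_id` column (`NA` until
#'   [find_subnetworks()] is applied); attributes `T`, `group_label`,
#'   `group_size`, `n_components`.
#' @export
identify_core <- function(freq, T = 0.5, group_label = NULL) {
  stopifnot(inherits(freq, "dera_freq"))
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0 || T > 1)
    stop("T must be a single value in (0, 1]")
  core <- freq[freq$frequency >= T, , drop = FALSE]
  core <- as.data.frame(core)
  rownames(core) <- NULL
  core$component_id <- rep(NA_integer_, nrow(core))
  attr(core, "T") <- T
  attr(core, "group_label") <- group_label
  attr(core, "group_size") <- attr(freq, "group_size")
  attr(core, "n_components") <- NA_integer_
  class(core) <- c("dera_core", "data.frame")
  core
}

#' Decompose a core regulation set into subnetworks
#'
#' Builds the undirected graph whose vertices are the genes incident to
#' core instances and whose edges are the instances' regulations; its
#' connected components are the subnetworks. Components are numbered with
#' contiguous integers starting at 1, ordered by decreasing component size
#' (number of genes) with ties broken by the lexicographically smallest
#' member gene.
#'
#' @param core a `dera_core` set (may be empty).
#' @return the same `dera_core` with `component_id` filled and attribute
#'   `n_components` set.
#' @export
find_subnetworks <- function(core) {
  stopifnot(inherits(core, "dera_core"))
  if (nrow(core) == 0L) {
    attr(core, "n_components") <- 0L
    return(core)
  }
  g <- igraph::graph_from_data_frame(
    core[, c("source", "target")], directed = FALSE,
    vertices = unique(c(core$source, core$target)))
  comp <- igraph::components(g)
  member <- comp$membership  # named by gene
  # renumber: decreasing size, ties by lexicographically smallest gene
  min_gene <- vapply(seq_len(comp$no), function(i)
    min(names(member)[member == i]), character(1L))
  ord <- order(-comp$csize, min_gene)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  core$component_id <- as.integer(relabel[member[core$source]])
  attr(core, "n_components") <- comp$no
  core
}

#' @export
print.dera_core <- function(x, ...) {
  lbl <- attr(x, "group_label")
  cat("Core regulation set", if (!is.null(lbl)) paste0("for group ",
      sQuote(lbl)), "\n")
  cat("  ", nrow(x), " core regulation instance(s) at T = ", attr(x, "T"),
      " over ", attr(x, "group_size"), " samples\n", sep = "")
  nc <- attr(x, "n_components")
  if (!is.na(nc)) cat("  subnetworks (connected components):", nc, "\n")
  if (nrow(x) > 0L) {
    cat("  genes involved:", length(unique(c(x$source, x$target))), "\n")
    print(utils::head(as.data.frame(x), 10L))
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  }
  invisible(x)
}

#' Group-specific core regulations
#'
#' Returns the target group's core instances absent from every other
#' group's core set. By default specificity is at the instance level: the
#' same edge carried with a different sign pattern in another group does
#' not disqualify (an edge up-regulated in one subtype and down-regulated
#' in another is a subtype-specific finding). `level = "edge"` collapses to
#' (source, effect, target) before comparing.
#'
#' @param core_target a `dera_core`.
#' @param core_others list of `dera_core` sets for the other groups.
#' @param level `"instance"` (default) or `"edge"`.
#' @return data frame of the target-specific instances (subset of
#'   `core_target` rows).
#' @export
group_specific <- function(core_target, core_others,
                           level = c("instance", "edge")) {
  level <- match.arg(level)
  stopifnot(inherits(core_target, "dera_core"))
  if (inherits(core_others, "dera_core")) core_others <- list(core_others)
  keyfun <- if (level == "instance") {
    function(x) paste(x$source, x$effect, x$target, x$source_state,
                      sep = "\r")
  } else {
    function(x) paste(x$source, x$effect, x$target, sep = "\r")
  }
  other_keys <- unlist(lapply(core_others, keyfun), use.names = FALSE)
  out <- core_target[!(keyfun(core_target) %in% other_keys), , drop = FALSE]
  out <- as.data.frame(out)
  rownames(out) <- NULL
  out
}

#' Validate a discovery core set in an independent cohort
#'
#' Computes the validation cohort's core set at `T_validation` and
#' intersects it with the discovery core at the instance level (or edge
#' level). Composition across several validation cohorts ("validated in
#' one or both") is explicit caller logic via union/intersection of the
#' returned validated sets.
#'
#' @param core_discovery a `dera_core` from the discovery cohort.
#' @param cohort_nets `dera_sample_networks` of the validation cohort.
#' @param T_validation prevalence threshold for the validation cohort,
#'   in (0, 1].
#' @param level `"instance"` (default) or `"edge"` equality.
#' @return list with `validated` (subset of discovery rows) and `report`
#'   (one row per discovery instance: `discovery_frequency`,
#'   `validation_frequency` -- the instance's frequency in the validation
#'   cohort whether or not it reaches `T_validation` -- and `validated`).
#' @export
cross_cohort_validate <- function(core_discovery, cohort_nets, T_validation,
                                  level = c("instance", "edge")) {
  level <- match.arg(level)
  stopifnot(inherits(core_discovery, "dera_core"))
  if (length(cohort_nets) == 0L) stop("empty validation cohort")
  vfreq <- frequency_table(cohort_nets)
  vcore <- identify_core(vfreq, T_validation)
  keyfun <- if (level == "instance") {
    function(x) paste(x$source, x$effect, x$target, x$source_state,
                      sep = "\r")
  } else {
    function(x) paste(x$source, x$effect, x$target, sep = "\r")
  }
  dkey <- keyfun(core_discovery)
  validated_flag <- dkey %in% keyfun(vcore)
  vf <- stats::setNames(vfreq$frequency, keyfun(vfreq))[dkey]
  vf[is.na(vf)] <- 0
  report <- data.frame(
    core_discovery[, INSTANCE_COLS, drop = FALSE],
    discovery_frequency = core_discovery$frequency,
    validation_frequency = unname(vf),
    validated = validated_flag,
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  validated <- as.data.frame(core_discovery)[validated_flag, , drop = FALSE]
  rownames(validated) <- NULL
  list(validated = validated, report = report)
}

#' Expression score of a regulation in one sample
#'
#' The expression of a regulation in a sample is the sum of its two genes'
#' log2 fold changes in that sample.
#'
#' @param fc log2 fold-change matrix, genes x tumors.
#' @param instance one-row data frame (or list) with at least `source` and
#'   `target`.
#' @param sample_id column of `fc`.
#' @return numeric scalar.
#' @export
regulation_expression <- function(fc, instance, sample_id) {
  src <- instance$source[1L]; tgt <- instance$target[1L]
  for (g in c(src, tgt))
    if (!g %in% rownames(fc)) stop("gene missing from fold-change matrix: ", g)
  if (!sample_id %in% colnames(fc)) stop("unknown sample ID: ", sample_id)
  unname(fc[src, sample_id] + fc[tgt, sample_id])
}

#' Core-set size over a grid of thresholds
#'
#' Counts core instances at each threshold in `T_grid`; by threshold
#' monotonicity the size sequence is non-increasing in T (asserted).
#'
#' @param freq a `dera_freq` table.
#' @param T_grid numeric vector of thresholds, each in (0, 1].
#' @return data frame `(T, size)`, sorted by `T`.
#' @export
t_sweep <- function(freq, T_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(freq, "dera_freq"))
  if (any(T_grid <= 0 | T_grid > 1)) stop("all T values must be in (0, 1]")
  T_grid <- sort(T_grid)
  size <- vapply(T_grid, function(T) sum(freq$frequency >= T), integer(1L))
  stopifnot(all(diff(size) <= 0L))
  data.frame(T = T_grid, size = size)
}

#' Write a core regulation set as TSV (plus SIF and node attributes)
#'
#' Writes the canonical TSV
#' `source effect target source_state target_state count frequency
#' component_id`, and optionally a SIF3 edge file and a `gene<TAB>state`
#' node-attribute TSV for network viewers. All outputs have deterministic
#' (sorted) row order.
#'
#' @param core a `dera_core`.
#' @param path output TSV path.
#' @param sif_path,nodes_path optional extra outputs.
#' @return `path`, invisibly.
#' @export
write_core_set <- function(core, path, sif_path = NULL, nodes_path = NULL) {
  stopifnot(inherits(core, "dera_core"))
  df <- as.data.frame(core)[, c(INSTANCE_COLS, "count", "frequency",
                                "component_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sif_path))
    writeLines(paste(df$source, df$effect, df$target, sep = "\t"), sif_path)
  if (!is.null(nodes_path)) {
    nodes <- rbind(
      data.frame(gene = df$source, state = df$source_state),
      data.frame(gene = df$target, state = df$target_state))
    nodes <- unique(nodes)
    nodes <- nodes[order(nodes$gene, nodes$state), , drop = FALSE]
    utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
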