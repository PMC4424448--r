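#' Read a phenotype table
#'
#' Two-column TSV `sample_id<TAB>group`. A reserved group token (default
#' `"REFERENCE"`) marks the control samples used to define baseline
#' expression.
#'
#' @param path file path.
#' @return data frame with columns `sample_id` and `group`.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 2L) stop("phenotype table must have exactly 2 columns")
  names(df) <- c("sample_id", "group")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample IDs in phenotype table")
  df
}

#' Differentially expressed regulation analysis for one phenotype group
#'
#' The full discovery pipeline: restrict the prior network and the
#' expression matrix to their common gene universe, compute per-sample log2
#' fold changes of the group's samples against the reference set,
#' discretize at fold-change cutoff `K` into a ternary gene-activity
#' indicator, overlay each sample's indicator column on the network keeping
#' sign-consistent regulations only, tally regulation instances across the
#' group, threshold at prevalence `T` to obtain the core regulation set,
#' and decompose it into connected subnetworks.
#'
#' @param network a `dera_network` prior network (see [read_network()]).
#' @param expression numeric genes x samples matrix on the log2 scale
#'   (attribute `scale` not `"RAW"`), covering the group's samples and the
#'   reference samples; see [read_expression()] and [preprocess()].
#' @param phenotype data frame with columns `sample_id`, `group`.
#' @param group phenotype group to analyze.
#' @param reference_label group token marking reference/control samples.
#' @param K fold-change cutoff on the linear scale (default 2, the
#'   conventional two-fold difference).
#' @param T core prevalence threshold in (0, 1] (default 0.5).
#' @return object of class `dera`: list with `network` (restricted prior),
#'   `fold_change`, `indicator`, `sample_networks`, `frequencies`
#'   (`dera_freq`), `core` (`dera_core`, subnetworks assigned), and
#'   `params`.
#' @examples
#' spec <- synthetic_spec(groups = c(case = 20L),
#'                        planted = data.frame(group = "case", n = 3,
#'                                             prevalence = 0.8))
#' co <- generate_cohort(spec, seed = 1)
#' fit <- dera(co$network, co$expression, co$phenotype, group = "case")
#' fit
#' @export
dera <- function(network, expression, phenotype, group,
                 reference_label = "REFERENCE", K = 2, T = 0.5) {
  stopifnot(inherits(network, "dera_network"))
  .check_expr(expression)
  tumor_ids <- phenotype$sample_id[phenotype$group == group]
  ref_ids <- phenotype$sample_id[phenotype$group == reference_label]
  if (length(tumor_ids) == 0L) stop("no samples in group ", sQuote(group))
  if (length(ref_ids) == 0L)
    stop("no reference samples (label ", sQuote(reference_label), ")")
  missing_samples <- setdiff(c(tumor_ids, ref_ids), colnames(expression))
  if (length(missing_samples) > 0L)
    stop("phenotype sample(s) absent from expression matrix: ",
         paste(utils::head(missing_samples, 5L), collapse = ", "))
  shared <- intersect(network$genes, rownames(expression))
  net <- if (length(shared) > 0L && length(shared) < length(network$genes))
    suppressWarnings(restrict_to_genes(network, shared)) else network
  fc <- fold_change(expression, tumor_ids, ref_ids)
  ind <- indicator(fc, K)
  nets <- induce_all(net, ind, quiet = TRUE)
  freq <- frequency_table(nets)
  core <- find_subnetworks(identify_core(freq, T, group_label = group))
  structure(list(network = net, fold_change = fc, indicator = ind,
                 sample_networks = nets, frequencies = freq, core = core,
                 params = list(group = group,
                               reference_label = reference_label,
                               K = K, T = T,
                               n_samples = length(tumor_ids),
                               n_reference = length(ref_ids))),
            class = "dera")
}

#' @export
print.dera <- function(x, ...) {
  p <- x$params
  cat("DERA analysis of group ", sQuote(p$group), ": ", p$n_samples,
      " samples vs ", p$n_reference, " reference samples\n", sep = "")
  cat("  prior network: ", nrow(x$network$regulations), " regulations, ",
      length(x$network$genes), " genes\n", sep = "")
  cat("  cutoff K = ", p$K, ", threshold T = ", p$T, "\n", sep = "")
  sizes <- vapply(x$sample_networks, nrow, integer(1L))
  cat("  sample-network sizes: min ", min(sizes), ", median ",
      stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  cat("  core regulations: ", nrow(x$core), " in ",
      attr(x$core, "n_components"), " subnetwork(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.dera <- function(object, ...) {
  print(object)
  cat("\nCore regulation set:\n")
  print(object$core)
  invisible(object)
}

#' Plot a DERA result
#'
#' `which = "sweep"` draws the core-set size as a function of the
#' prevalence threshold T (the size is non-increasing in T).
#' `which = "core"` draws the core regulation graph: red nodes are
#' over-expressed genes, green under-expressed; arrows are activations,
#' blunt (dashed) edges inhibitions; components are laid out jointly.
#'
#' @param x a `dera` object.
#' @param which `"sweep"` or `"core"`.
#' @param T_grid thresholds for the sweep panel.
#' @param ... passed to the underlying plot call.
#' @export
plot.dera <- function(x, which = c("sweep", "core"),
                      T_grid = seq(0.05, 0.95, by = 0.05), ...) {
  which <- match.arg(which)
  if (which == "sweep") {
    sw <- t_sweep(x$frequencies, T_grid)
    plot(sw$T, sw$size, type = "s", xlab = "prevalence threshold T",
         ylab = "core regulations", ...)
    graphics::abline(v = x$params$T, lty = 3)
    return(invisible(sw))
  }
  core <- x$core
  if (nrow(core) == 0L) {
    plot.new(); graphics::title("empty core set")
    return(invisible(NULL))
  }
  g <- igraph::graph_from_data_frame(
    core[, c("source", "target", "effect")], directed = TRUE)
  states <- stats::setNames(
    c(core$source_state, core$target_state),
    c(core$source, core$target))
  vcol <- ifelse(states[igraph::V(g)$name] > 0, "firebrick", "forestgreen")
  elty <- ifelse(igraph::E(g)$effect == "inhibition", 2, 1)
  igraph::plot.igraph(g, vertex.color = vcol, edge.lty = elty,
                      vertex.label.cex = 0.7, ...)
  invisible(g)
}
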