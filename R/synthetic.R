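# Synthetic cohorts provide ground truth for every upstream stage: a random
# signed prior network, planted sign-consistent regulations activated per
# sample with a controlled Bernoulli prevalence, and log-normal expression
# noise on the log2 scale.

#' Specify a synthetic cohort
#'
#' The generator emulates the structure assumed by the method: log2-scale
#' expression, a reference sample set defining baseline, and planted
#' regulations whose both genes are shifted sign-consistently in a random
#' subset of a group's samples.
#'
#' Planting is given as a recipe: one row per planted regulation requesting
#' a `group` (a group label, or `"shared"` for all groups) and a
#' `prevalence` in [0, 1]. Planted edges are laid down on pairwise-disjoint
#' random gene pairs (so shifts never overlap) with a random sign pattern
#' consistent with the edge effect, and the remaining background edges
#' avoid pairs lying entirely within the planted gene set, so no prior edge
#' can ride on the planted signal and distort the nominal prevalences; the
#' drawn instances are recorded in the cohort's `truth`. Alternatively
#' `planted` may be an explicit instance data frame with columns `source`,
#' `effect`, `target`, `source_state`, `target_state`, `group`,
#' `prevalence` (symbols from the `G%03d` synthetic universe): the
#' instances are checked for sign consistency and built into the generated
#' network under the same background-exclusion rule.
#'
#' @param n_genes,n_edges size of the random prior network (no self-loops
#'   are generated; self-loop behaviour is exercised separately).
#' @param inhibition_fraction fraction of edges drawn as inhibitions.
#' @param groups named integer vector: group label -> number of samples.
#' @param n_reference number of reference (control) samples.
#' @param planted data frame; recipe form has columns `group`, `n`,
#'   `prevalence` (one row per batch of planted instances), explicit form
#'   as described above. `NULL` plants nothing.
#' @param effect_size_log2 mean absolute log2 shift injected into the two
#'   genes of an active planted regulation. The default 2.0 is one log2
#'   unit above the conventional two-fold indicator cutoff, making planted
#'   signal detectable by construction.
#' @param noise_sd_log2 SD of the i.i.d. Gaussian noise added to every
#'   log2 expression value (default 0.3, a typical array-scale residual).
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensities are
#'   drawn once as `N(baseline_mean, baseline_sd)` and shared by all
#'   samples; fold changes cancel the baseline, so these only set the scale
#'   of the raw matrix.
#' @return list of class `dera_synth_spec`.
#' @export
synthetic_spec <- function(n_genes = 30L, n_edges = 50L,
                           inhibition_fraction = 0.3,
                           groups = c(case = 40L),
                           n_reference = 10L,
                           planted = NULL,
                           effect_size_log2 = 2.0,
                           noise_sd_log2 = 0.3,
                           baseline_mean = 8, baseline_sd = 1) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector: label -> sample count")
  if (n_edges > n_genes * (n_genes - 1L))
    stop("n_edges exceeds the number of possible directed non-loop edges")
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    if (any(planted$prevalence < 0 | planted$prevalence > 1))
      stop("prevalences must be in [0, 1]")
    ok_groups <- c(names(groups), "shared")
    if (any(!planted$group %in% ok_groups))
      stop("planted group labels must be group names or 'shared'")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_edges = as.integer(n_edges),
                 inhibition_fraction = inhibition_fraction,
                 groups = groups, n_reference = as.integer(n_reference),
                 planted = planted,
                 effect_size_log2 = effect_size_log2,
                 noise_sd_log2 = noise_sd_log2,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "dera_synth_spec")
}

# Draw the network and concrete planted instances from the structure RNG.
#
# With a planting recipe the planted edges are laid down first on
# pairwise-disjoint random gene pairs, and the remaining edges are sampled
# from ordered non-loop pairs with at most one endpoint among the planted
# genes. This guarantees (a) the planting is always embeddable and (b) the
# planted gene set induces exactly the planted edges, so no prior edge can
# ride on the planted signal and distort the nominal prevalences.
.synth_structure <- function(spec) {
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  planted <- spec$planted
  has_planted <- !is.null(planted) && nrow(planted) > 0L
  recipe <- has_planted && !"source" %in% names(planted)
  planted_edges <- NULL
  if (has_planted && !recipe) {
    # explicit instances: validate, then build them into the network
    if (any(!c(planted$source, planted$target) %in% genes))
      stop("planted gene(s) not present in the synthetic gene universe")
    consistent <- ifelse(planted$effect == "activation",
                         planted$source_state == planted$target_state,
                         planted$source_state == -planted$target_state)
    if (any(!consistent))
      stop("planted instance(s) violate sign consistency")
    if (nrow(planted) > spec$n_edges)
      stop("more planted instances than network edges")
    planted_edges <- unique(planted[, c("source", "effect", "target")])
  }
  if (recipe) {
    total_n <- sum(planted$n)
    if (2L * total_n > spec$n_genes)
      stop("cannot embed planted instances: need ", 2L * total_n,
           " distinct genes for gene-disjoint planting, have ",
           spec$n_genes)
    if (total_n > spec$n_edges)
      stop("more planted instances than network edges")
    pg <- sample(genes, 2L * total_n)
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(planted))) {
      for (j in seq_len(planted$n[i])) {
        k <- k + 1L
        eff <- if (stats::runif(1L) < spec$inhibition_fraction)
          "inhibition" else "activation"
        s_state <- sample(c(-1L, 1L), 1L)
        t_state <- if (eff == "activation") s_state else -s_state
        rows[[k]] <- data.frame(
          source = pg[2L * k - 1L], effect = eff, target = pg[2L * k],
          source_state = s_state, target_state = t_state,
          group = planted$group[i], prevalence = planted$prevalence[i],
          stringsAsFactors = FALSE)
      }
    }
    planted <- do.call(rbind, rows)
    planted_edges <- planted[, c("source", "effect", "target")]
  }
  # candidate ordered non-loop pairs for the remaining (background) edges
  src_i <- rep(seq_len(spec$n_genes), each = spec$n_genes)
  tgt_i <- rep(seq_len(spec$n_genes), times = spec$n_genes)
  ok <- src_i != tgt_i
  if (has_planted) {
    in_planted <- genes %in% c(planted$source, planted$target)
    ok <- ok & !(in_planted[src_i] & in_planted[tgt_i])
  }
  src_i <- src_i[ok]; tgt_i <- tgt_i[ok]
  n_rest <- spec$n_edges - if (has_planted) nrow(planted_edges) else 0L
  if (n_rest > length(src_i))
    stop("n_edges too large for the non-confounding background pair pool")
  take <- sample.int(length(src_i), n_rest)
  effect <- ifelse(stats::runif(n_rest) < spec$inhibition_fraction,
                   "inhibition", "activation")
  src <- genes[src_i[take]]; tgt <- genes[tgt_i[take]]
  if (has_planted) {
    src <- c(planted_edges$source, src)
    tgt <- c(planted_edges$target, tgt)
    effect <- c(planted_edges$effect, effect)
  }
  net <- regulatory_network(src, effect, tgt)
  if (!has_planted)
    return(list(network = net, planted = NULL))
  rownames(planted) <- NULL
  list(network = net, planted = planted)
}

#' Generate a synthetic cohort with planted regulations
#'
#' Builds (1) a random signed prior network; (2) reference samples as
#' per-gene baseline plus noise; (3) group samples in which each planted
#' regulation assigned to the group (or `"shared"`) is independently
#' activated with probability equal to its prevalence -- when active, the
#' source gene is shifted by `source_state * effect_size_log2` and the
#' target by `target_state * effect_size_log2`; (4) i.i.d. Gaussian noise
#' on every value. Non-planted genes carry baseline plus noise only.
#'
#' Regeneration with the same spec and seeds is bit-for-bit identical. Two
#' cohorts sharing `structure_seed` but differing in `seed` share the
#' network and the concrete planted instances while drawing independent
#' activations and noise -- the setting for cross-cohort validation
#' experiments.
#'
#' @param spec a `dera_synth_spec`.
#' @param seed integer seed for activations and noise.
#' @param structure_seed integer seed for the network and the concrete
#'   planted instances; defaults to `seed`.
#' @return list of class `dera_synth_cohort`: `network` (`dera_network`),
#'   `expression` (log2 genes x samples matrix covering all groups and the
#'   reference samples), `phenotype` (data frame `sample_id`, `group`;
#'   reference samples labeled `"REFERENCE"`), `truth` (planted instance
#'   data frame with `group` and `prevalence`, or `NULL`), and `spec`.
#' @export
generate_cohort <- function(spec, seed, structure_seed = seed) {
  stopifnot(inherits(spec, "dera_synth_spec"))
  set.seed(as.integer(structure_seed))
  struct <- .synth_structure(spec)
  net <- struct$network
  planted <- struct$planted
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean,
                           spec$baseline_sd)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  group_labels <- rep(names(spec$groups), spec$groups)
  sample_ids <- c(
    sprintf("%s_%02d", group_labels,
            unlist(lapply(spec$groups, seq_len), use.names = FALSE)),
    sprintf("REF_%02d", seq_len(spec$n_reference)))
  pheno <- data.frame(sample_id = sample_ids,
                      group = c(group_labels,
                                rep("REFERENCE", spec$n_reference)),
                      stringsAsFactors = FALSE)
  n_samples <- length(sample_ids)
  expr <- matrix(baseline, spec$n_genes, n_samples,
                 dimnames = list(genes, sample_ids))
  truth <- NULL
  if (!is.null(planted)) {
    n_tumor <- length(group_labels)
    for (i in seq_len(nrow(planted))) {
      in_group <- if (planted$group[i] == "shared") rep(TRUE, n_tumor)
                  else group_labels == planted$group[i]
      active <- in_group &
        stats::runif(n_tumor) < planted$prevalence[i]
      cols <- which(active)
      expr[planted$source[i], cols] <- expr[planted$source[i], cols] +
        planted$source_state[i] * spec$effect_size_log2
      expr[planted$target[i], cols] <- expr[planted$target[i], cols] +
        planted$target_state[i] * spec$effect_size_log2
    }
    truth <- planted
  }
  expr <- expr + matrix(stats::rnorm(length(expr), 0, spec$noise_sd_log2),
                        nrow(expr))
  attr(expr, "scale") <- "LOG2"
  structure(list(network = net, expression = expr, phenotype = pheno,
                 truth = truth, spec = spec),
            class = "dera_synth_cohort")
}

#' @export
print.dera_synth_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$expression), "genes,",
      ncol(x$expression), "samples (",
      sum(x$phenotype$group == "REFERENCE"), "reference )\n")
  print(x$network)
  if (!is.null(x$truth))
    cat("  planted instances:", nrow(x$truth), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the network (SIF3), expression (TSV), phenotype (TSV) and, when
#' present, the planted-truth table (TSV) under `dir`.
#'
#' @param cohort a `dera_synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dera_synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(cohort$network, file.path(dir, "network.sif"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$phenotype, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
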