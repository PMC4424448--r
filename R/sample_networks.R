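# A regulation instance is a regulation plus the concrete sign pattern of
# its two genes in one sample: (source, effect, target, source_state,
# target_state). Sets of instances travel as data frames with exactly these
# five columns; instance identity is the full quadruple (target_state is
# implied by sign-consistency but stored for clarity).

INSTANCE_COLS <- c("source", "effect", "target", "source_state", "target_state")

.empty_instances <- function() {
  data.frame(source = character(0), effect = character(0),
             target = character(0), source_state = integer(0),
             target_state = integer(0), stringsAsFactors = FALSE)
}

# Canonical single-string key for instance identity.
instance_key <- function(inst) {
  if (nrow(inst) == 0L) return(character(0))
  paste(inst$source, inst$effect, inst$target, inst$source_state, sep = "\r")
}

.sort_instances <- function(inst) {
  o <- order(inst$source, inst$target, inst$effect, inst$source_state)
  inst <- inst[o, , drop = FALSE]
  rownames(inst) <- NULL
  inst
}

#' Induce the sample-specific regulation network of one tumor
#'
#' Overlays one sample's indicator column on the prior network and keeps a
#' regulation iff both endpoint genes are differentially expressed with
#' signs consistent with the edge effect: for an activation both genes must
#' share the sign (both over- or both under-expressed); for an inhibition
#' the signs must be opposite. A gene with indicator 0, or absent from the
#' indicator matrix altogether, never supports an instance. Self-inhibition
#' edges can never be sign-consistent and are therefore structurally
#' excluded.
#'
#' @param net a `dera_network` prior network.
#' @param ind integer indicator matrix, genes x samples (entries in
#'   `{-1, 0, 1}`), from [indicator()].
#' @param sample_id column of `ind` to overlay.
#' @return data frame of regulation instances (columns `source`, `effect`,
#'   `target`, `source_state`, `target_state`), rows sorted; attribute
#'   `sample_id`.
#' @export
induce_sample_network <- function(net, ind, sample_id) {
  stopifnot(inherits(net, "dera_network"))
  if (!sample_id %in% colnames(ind))
    stop("unknown sample ID: ", sample_id)
  reg <- net$regulations
  col <- ind[, sample_id]
  state <- stats::setNames(as.integer(col), rownames(ind))
  a <- state[reg$source]
  b <- state[reg$target]
  a[is.na(a)] <- 0L   # network genes missing from the indicator: state 0
  b[is.na(b)] <- 0L
  keep <- a != 0L & b != 0L &
    ifelse(reg$effect == "activation", a == b, a == -b)
  inst <- data.frame(source = reg$source[keep], effect = reg$effect[keep],
                     target = reg$target[keep],
                     source_state = unname(a[keep]),
                     target_state = unname(b[keep]),
                     stringsAsFactors = FALSE)
  inst <- .sort_instances(inst)
  attr(inst, "sample_id") <- sample_id
  inst
}

#' Induce sample-specific networks for every sample
#'
#' Applies [induce_sample_network()] to every column of the indicator
#' matrix. Network genes absent from the indicator matrix are treated as
#' state 0 and reported once via a warning.
#'
#' @inheritParams induce_sample_network
#' @param quiet suppress the missing-genes warning.
#' @return named list (one element per sample, column order preserved) of
#'   instance data frames; class `dera_sample_networks`.
#' @export
induce_all <- function(net, ind, quiet = FALSE) {
  stopifnot(inherits(net, "dera_network"))
  if (ncol(ind) == 0L) stop("indicator matrix has no samples")
  missing_genes <- setdiff(net$genes, rownames(ind))
  if (length(missing_genes) > 0L && !quiet)
    warning(length(missing_genes), " network gene(s) absent from the ",
            "indicator matrix are treated as unchanged (state 0)")
  nets <- lapply(colnames(ind), function(s)
    induce_sample_network(net, ind, s))
  names(nets) <- colnames(ind)
  class(nets) <- "dera_sample_networks"
  nets
}

#' @export
print.dera_sample_networks <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1L))
  cat("Sample-specific regulation networks for", length(x), "samples\n")
  cat("  instances per sample: min", min(sizes), " median",
      stats::median(sizes), " max", max(sizes), "\n")
  invisible(x)
}

#' Export sample networks as one long-format TSV
#'
#' Writes `sample<TAB>source<TAB>effect<TAB>target<TAB>source_state<TAB>`
#' `target_state`, samples in list order, instances sorted within sample.
#'
#' @param nets a `dera_sample_networks` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_networks <- function(nets, path) {
  rows <- lapply(names(nets), function(s) {
    inst <- nets[[s]]
    if (nrow(inst) == 0L) return(NULL)
    cbind(sample = s, inst)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(sample = character(0), .empty_instances())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
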