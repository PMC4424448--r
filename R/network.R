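# Canonical effect labels used throughout the package.
EFFECTS <- c("activation", "inhibition")

# Tokens accepted on input (matched case-insensitively).
.activation_tokens <- c("activation", "activates", "->", "1", "+")
.inhibition_tokens <- c("inhibition", "inhibits", "-|", "-1", "-")

.normalize_effect <- function(token) {
  tok <- tolower(token)
  out <- rep(NA_character_, length(tok))
  out[tok %in% .activation_tokens] <- "activation"
  out[tok %in% .inhibition_tokens] <- "inhibition"
  out
}

#' Construct a prior signed regulatory network
#'
#' A regulatory network is a set of signed directed edges ("regulations"),
#' each one stating that a source gene activates or inhibits a target gene.
#' A regulation is identified by the triple (source, target, effect), so the
#' same gene pair may carry both an activation and an inhibition edge;
#' both are kept and evaluated independently downstream.
#'
#' @param source,target character vectors of gene symbols. Symbols are opaque
#'   case-sensitive strings; no normalization is attempted.
#' @param effect character vector; each entry one of `"activation"` or
#'   `"inhibition"` (or an accepted synonym, see [read_network()]).
#' @return An object of class `dera_network`: a list with elements
#'   `regulations` (data frame with columns `source`, `effect`, `target`,
#'   duplicates collapsed, rows sorted), `genes` (the gene universe: every
#'   symbol appearing as a source or target), and counts `n_duplicates`
#'   (collapsed duplicate rows), `n_contradictory` (gene pairs carrying both
#'   effects) and `n_self_loops`.
#' @examples
#' net <- regulatory_network(c("A", "B"), c("activation", "inhibition"),
#'                           c("B", "C"))
#' net
#' @seealso [read_network()], [restrict_to_genes()]
#' @export
regulatory_network <- function(source, effect, target) {
  source <- as.character(source)
  effect <- as.character(effect)
  target <- as.character(target)
  n <- length(source)
  if (length(effect) != n || length(target) != n)
    stop("source, effect and target must have equal length")
  if (n == 0L) stop("empty network: no regulations given")
  if (any(!nzchar(source)) || any(!nzchar(target)))
    stop("gene symbols must be non-empty strings")
  eff <- .normalize_effect(effect)
  if (anyNA(eff)) {
    bad <- unique(effect[is.na(eff)])
    stop("unknown effect token(s): ", paste(sQuote(bad), collapse = ", "))
  }
  reg <- data.frame(source = source, effect = eff, target = target,
                    stringsAsFactors = FALSE)
  n_before <- nrow(reg)
  reg <- unique(reg)
  reg <- reg[order(reg$source, reg$target, reg$effect), , drop = FALSE]
  rownames(reg) <- NULL
  # contradictory pairs: same (source, target) with both effects
  pair <- paste(reg$source, reg$target, sep = "\r")
  tab <- table(pair)
  structure(list(
    regulations = reg,
    genes = sort(unique(c(reg$source, reg$target))),
    n_duplicates = n_before - nrow(reg),
    n_contradictory = sum(tab == 2L),
    n_self_loops = sum(reg$source == reg$target)
  ), class = "dera_network")
}

#' @export
print.dera_network <- function(x, ...) {
  cat("Signed regulatory network:", nrow(x$regulations), "regulations over",
      length(x$genes), "genes\n")
  cat("  activation:", sum(x$regulations$effect == "activation"),
      " inhibition:", sum(x$regulations$effect == "inhibition"), "\n")
  if (x$n_duplicates > 0)
    cat("  duplicates collapsed on input:", x$n_duplicates, "\n")
  if (x$n_contradictory > 0)
    cat("  contradictory pairs (both effects kept):", x$n_contradictory, "\n")
  if (x$n_self_loops > 0)
    cat("  self-loops:", x$n_self_loops, "\n")
  invisible(x)
}

#' Read a signed regulatory network from a text file
#'
#' Two dialects are supported. `"SIF3"` is a whitespace- or tab-separated
#' three-column format `source effect target`; lines starting with `#` are
#' comments and blank lines are skipped. `"TSV_HEADER"` is tab-separated with
#' a header line `source<TAB>effect<TAB>target`. Accepted effect tokens
#' (case-insensitive): activation -- `activation`, `activates`, `->`, `1`,
#' `+`; inhibition -- `inhibition`, `inhibits`, `-|`, `-1`, `-`.
#'
#' Duplicate (source, target, effect) triples are collapsed (their count is
#' stored on the returned object); a pair carrying both an activation and an
#' inhibition yields two distinct regulations, both retained.
#'
#' @param path path to the network file.
#' @param dialect `"SIF3"` (default) or `"TSV_HEADER"`.
#' @return A `dera_network`; see [regulatory_network()].
#' @export
read_network <- function(path, dialect = c("SIF3", "TSV_HEADER")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  if (dialect == "TSV_HEADER") {
    if (length(lines) == 0L) stop("empty network file: ", path)
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(tolower(hdr), c("source", "effect", "target")))
      stop("expected header 'source\\teffect\\ttarget' in ", path)
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) stop("empty network: no regulations in ", path)
  split_re <- if (dialect == "SIF3") "[ \t]+" else "\t"
  fields <- strsplit(trimws(lines), split_re)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- lineno[which(nf != 3L)[1L]]
    stop("malformed line ", bad, ": expected 3 fields, got ",
         nf[which(nf != 3L)[1L]])
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  eff <- .normalize_effect(m[, 2L])
  if (anyNA(eff)) {
    i <- which(is.na(eff))[1L]
    stop("line ", lineno[i], ": unknown effect token ", sQuote(m[i, 2L]))
  }
  regulatory_network(m[, 1L], eff, m[, 3L])
}

#' Write a network as canonical SIF3
#'
#' Emits `source<TAB>effect<TAB>target` rows with canonical effect tokens
#' `activation`/`inhibition`, sorted by (source, target, effect), so output
#' is byte-stable and round-trips through [read_network()].
#'
#' @param net a `dera_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "dera_network"))
  reg <- net$regulations
  reg <- reg[order(reg$source, reg$target, reg$effect), , drop = FALSE]
  writeLines(paste(reg$source, reg$effect, reg$target, sep = "\t"), path)
  invisible(path)
}

#' Restrict a network to a gene universe
#'
#' Keeps regulations with both endpoints in `genes`; used before indicator
#' overlay so the network and the expression matrix share a gene universe.
#'
#' @param net a `dera_network`.
#' @param genes character vector of gene symbols to keep.
#' @return A `dera_network` containing the surviving regulations, with
#'   attribute `n_dropped` giving the number of regulations removed. If no
#'   regulation survives, an empty network is returned with a warning (the
#'   downstream overlay handles empty networks).
#' @export
restrict_to_genes <- function(net, genes) {
  stopifnot(inherits(net, "dera_network"))
  if (length(genes) == 0L) stop("genes must be non-empty")
  reg <- net$regulations
  keep <- reg$source %in% genes & reg$target %in% genes
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    warning("no regulation has both endpoints in the given gene set; ",
            "returning an empty network")
    out <- structure(list(
      regulations = reg[0L, , drop = FALSE],
      genes = character(0),
      n_duplicates = 0L, n_contradictory = 0L, n_self_loops = 0L
    ), class = "dera_network")
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  out <- regulatory_network(reg$source[keep], reg$effect[keep],
                            reg$target[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}
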