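# Preranked gene-set enrichment over per-transcript prognostic scores.

#' Read a gene-set collection from a GMT file
#'
#' Each line holds a set name, a description, then member gene symbols,
#' tab-separated. Symbols are uppercased for matching and duplicates within
#' a set are removed.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors with a `provenance` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", i, ": need name, description and >= 1 gene")
    }
    nms[i] <- parts[1]
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("malformed GMT line ", i, ": empty set")
    sets[[i]] <- genes
  }
  names(sets) <- nms
  attr(sets, "provenance") <- path
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written on every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Enrichment score of one set given the ranked weights.
# ranked_w: |score|^exponent in ranking order; pos: sorted hit positions.
# Returns the signed maximal deviation of the running sum from zero.
gsea_es <- function(ranked_w, pos, n_genes) {
  m <- length(pos)
  n_miss <- n_genes - m
  if (n_miss == 0) return(0)
  w <- ranked_w[pos]
  W <- sum(w)
  hit_frac <- if (W > 0) cumsum(w) / W else seq_len(m) / m
  miss_frac <- (pos - seq_len(m)) / n_miss
  up <- hit_frac - miss_frac         # running sum just after each hit
  down <- c(0, hit_frac[-m]) - miss_frac  # just before each hit
  hi <- max(up); lo <- min(down)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ranked by score in descending order (positive scores = poor
#' prognosis under this package's sign convention). For each set, the
#' enrichment score ES is the maximal deviation of a running sum that
#' increments at member genes proportionally to `|score|^weight_exponent`
#' and decrements uniformly at non-members. The null is built from `n_perm`
#' random gene-label permutations of the set membership (independent draws
#' per set); the nominal p-value is the one-sided tail frequency against the
#' null scores of matching sign, computed as `(1 + k) / (1 + m)` so that
#' p lies in (0, 1]; NES is ES divided by the mean |null ES| of the same
#' sign. Genes in sets but absent from the ranking are dropped; sets with
#' fewer matched genes than `min_size` are skipped.
#'
#' @param scores named numeric vector of per-gene prognostic scores.
#' @param sets a gene-set collection ([read_gmt()] or a named list).
#' @param n_perm number of permutations (default 1000).
#' @param weight_exponent exponent on `|score|` for hit increments
#'   (0 = classic/unweighted, 1 = weighted, the default).
#' @param min_size minimum number of matched genes per set (default 10).
#' @param seed integer seed for the permutation null.
#' @return an `enrichment_result` data frame with columns `set`, `size`,
#'   `ES`, `NES`, `p_nominal` and `leading_edge` (comma-separated gene
#'   symbols); skipped sets are recorded in the `skipped` attribute.
#' @export
preranked_gsea <- function(scores, sets, n_perm = 1000L, weight_exponent = 1,
                           min_size = 10L, seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  genes <- toupper(names(scores))
  o <- order(-scores, genes)      # descending score, stable name tie-break
  ranked_genes <- genes[o]
  ranked_w <- abs(scores[o])^weight_exponent
  n_genes <- length(ranked_genes)
  gene_index <- stats::setNames(seq_len(n_genes), ranked_genes)

  set_names <- names(sets)
  keep <- logical(length(sets))
  rows <- vector("list", length(sets))
  seeds <- derive_seeds(seed, length(sets))
  for (k in seq_along(sets)) {
    members <- unique(toupper(sets[[k]]))
    pos <- sort(unname(gene_index[members[members %in% ranked_genes]]))
    m <- length(pos)
    if (m < min_size || m == n_genes) next
    keep[k] <- TRUE
    es <- gsea_es(ranked_w, pos, n_genes)
    null_es <- with_seed(seeds[k], {
      vapply(seq_len(n_perm), function(i) {
        gsea_es(ranked_w, sort.int(sample.int(n_genes, m)), n_genes)
      }, numeric(1))
    })
    same <- null_es[sign(null_es) == sign(es)]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    le <- leading_edge(ranked_w, pos, n_genes, es, ranked_genes)
    rows[[k]] <- data.frame(set = set_names[k], size = m, ES = es, NES = nes,
                            p_nominal = p,
                            leading_edge = paste(le, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[keep])
  if (is.null(res)) {
    res <- data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), p_nominal = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  structure(res, skipped = set_names[!keep],
            class = c("enrichment_result", "data.frame"))
}

# Members up to (ES > 0) or from (ES < 0) the running-sum extremum.
leading_edge <- function(ranked_w, pos, n_genes, es, ranked_genes) {
  m <- length(pos)
  w <- ranked_w[pos]; W <- sum(w)
  hit_frac <- if (W > 0) cumsum(w) / W else seq_len(m) / m
  miss_frac <- (pos - seq_len(m)) / (n_genes - m)
  if (es >= 0) {
    j <- which.max(hit_frac - miss_frac)
    ranked_genes[pos[seq_len(j)]]
  } else {
    j <- which.min(c(0, hit_frac[-m]) - miss_frac)
    ranked_genes[pos[seq(j, m)]]
  }
}

#' Split enrichment results by direction of prognosis
#'
#' Positive-score-enriched sets (positive ES) are associated with poor
#' prognosis; negative-score-enriched sets with good prognosis. Each table
#' is ordered by nominal p, then by decreasing |NES|.
#'
#' @param results an `enrichment_result` from [preranked_gsea()].
#' @param bh add a Benjamini-Hochberg adjusted column per table (off by
#'   default; nominal p is the primary readout).
#' @return list with data frames `poor_prognosis` and `good_prognosis`.
#' @export
two_direction_report <- function(results, bh = FALSE) {
  split_dir <- function(d) {
    d <- d[order(d$p_nominal, -abs(d$NES), d$set), , drop = FALSE]
    rownames(d) <- NULL
    if (bh && nrow(d)) d$p_bh <- stats::p.adjust(d$p_nominal, "BH")
    d
  }
  list(poor_prognosis = split_dir(results[results$ES > 0, , drop = FALSE]),
       good_prognosis = split_dir(results[results$ES < 0, , drop = FALSE]))
}
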