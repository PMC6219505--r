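# Feature preparation: arm-level CNA dichotomization, mutation calls,
# frequency and significance-score filters.

#' Feature-preparation thresholds
#'
#' @param arm_cna_threshold absolute arm fraction at or beyond which a gain
#'   or loss is called (default 0.10).
#' @param min_frequency minimum alteration frequency for inclusion
#'   (default 0.05).
#' @param mutsig_p_threshold MutSig p-value cutoff for mutation features
#'   entering the risk model (default 0.1).
#' @param mutsig_q_threshold MutSig q-value cutoff for mutation calls
#'   (default 0.05).
#' @param gistic_p_threshold GISTIC p-value cutoff for copy-number features
#'   (default 0.25).
#' @param mki67_high_cutoff expression value at or above which MKI67 is
#'   called "high" (default 700, corresponding to a 15% labeling index).
#' @return a `feature_prep_config` list.
#' @export
feature_prep_config <- function(arm_cna_threshold = 0.10,
                                min_frequency = 0.05,
                                mutsig_p_threshold = 0.1,
                                mutsig_q_threshold = 0.05,
                                gistic_p_threshold = 0.25,
                                mki67_high_cutoff = 700) {
  vals <- c(arm_cna_threshold, min_frequency, mutsig_p_threshold,
            mutsig_q_threshold, gistic_p_threshold, mki67_high_cutoff)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(arm_cna_threshold = arm_cna_threshold,
                 min_frequency = min_frequency,
                 mutsig_p_threshold = mutsig_p_threshold,
                 mutsig_q_threshold = mutsig_q_threshold,
                 gistic_p_threshold = gistic_p_threshold,
                 mki67_high_cutoff = mki67_high_cutoff),
            class = "feature_prep_config")
}

#' Dichotomize arm-level copy-number fractions
#'
#' Arm-level copy number is summarized as a signed fraction of the arm
#' altered (gains positive, losses negative). A value at or beyond +0.10 is
#' a gain, at or beyond -0.10 a loss, anything strictly inside is neutral.
#'
#' @param arm_fractions numeric vector/matrix of signed fractions in
#'   `[-1, 1]`.
#' @param threshold absolute calling threshold (default 0.10).
#' @return character object of the same shape with values `"gain"`,
#'   `"loss"`, `"neutral"`.
#' @export
dichotomize_arm_cna <- function(arm_fractions, threshold = 0.10) {
  v <- arm_fractions
  if (any(v < -1 | v > 1, na.rm = TRUE)) {
    stop("arm fractions must lie in [-1, 1]")
  }
  out <- ifelse(v >= threshold, "gain",
                ifelse(v <= -threshold, "loss", "neutral"))
  if (!is.null(dim(v))) dim(out) <- dim(v)
  dimnames(out) <- dimnames(v)
  out
}

#' Assemble the risk model's feature matrix from raw tables
#'
#' Builds binary mutation features (either from a 0/1 matrix or from a
#' variant table where only amino-acid-changing variants count as
#' mutations), dichotomizes arm-level CNA fractions into per-arm gain/loss
#' indicators, applies the MutSig/GISTIC score filters when score tables
#' are provided, drops alteration features below the minimum frequency, and
#' appends protein and clinical covariates unchanged.
#'
#' @param mutations samples-by-genes binary matrix, or a data frame with
#'   columns `sample`, `gene` and `protein_change` (empty/NA
#'   `protein_change` = silent, not counted).
#' @param arm_cna optional samples-by-arms matrix of signed fractions.
#' @param mutsig optional data frame with columns `gene`, `p` and/or `q`;
#'   genes failing `q <= mutsig_q_threshold` (when `q` present) or
#'   `p <= mutsig_p_threshold` (when `p` present) are dropped.
#' @param gistic optional data frame with columns `arm`, `p`; arms failing
#'   `p <= gistic_p_threshold` are dropped.
#' @param protein optional samples-by-proteins numeric matrix.
#' @param clinical optional samples-by-covariates numeric matrix.
#' @param config a [feature_prep_config()].
#' @return a [feature_matrix()]; dropped feature names are recorded in the
#'   `dropped` attribute.
#' @export
prepare_features <- function(mutations, arm_cna = NULL, mutsig = NULL,
                             gistic = NULL, protein = NULL, clinical = NULL,
                             config = feature_prep_config()) {
  mut <- build_mutation_matrix(mutations)
  samples <- rownames(mut)
  check_alignment <- function(tab, what) {
    if (!is.null(tab) && !identical(rownames(tab), samples)) {
      stop("sample ids of ", what, " do not match the mutation table")
    }
  }
  check_alignment(arm_cna, "arm_cna")
  check_alignment(protein, "protein")
  check_alignment(clinical, "clinical")

  dropped <- character(0)

  if (!is.null(mutsig)) {
    bad <- if ("q" %in% names(mutsig)) {
      mutsig$gene[!(mutsig$q <= config$mutsig_q_threshold)]
    } else {
      mutsig$gene[!(mutsig$p <= config$mutsig_p_threshold)]
    }
    hit <- colnames(mut) %in% bad
    dropped <- c(dropped, colnames(mut)[hit])
    mut <- mut[, !hit, drop = FALSE]
  }

  cna_bin <- NULL
  if (!is.null(arm_cna)) {
    if (!is.null(gistic)) {
      bad_arm <- gistic$arm[!(gistic$p <= config$gistic_p_threshold)]
      hit <- colnames(arm_cna) %in% bad_arm
      dropped <- c(dropped, colnames(arm_cna)[hit])
      arm_cna <- arm_cna[, !hit, drop = FALSE]
    }
    if (ncol(arm_cna)) {
      calls <- dichotomize_arm_cna(arm_cna, config$arm_cna_threshold)
      gain <- (calls == "gain") * 1
      loss <- (calls == "loss") * 1
      colnames(gain) <- paste0(colnames(arm_cna), "_gain")
      colnames(loss) <- paste0(colnames(arm_cna), "_loss")
      cna_bin <- cbind(gain, loss)
    }
  }

  freq_filter <- function(m) {
    if (is.null(m) || !ncol(m)) return(m)
    freq <- colMeans(m)
    low <- freq < config$min_frequency
    dropped <<- c(dropped, colnames(m)[low])
    m[, !low, drop = FALSE]
  }
  mut <- freq_filter(mut)
  cna_bin <- freq_filter(cna_bin)

  blocks <- list(mut, cna_bin, protein, clinical)
  kinds <- c(rep("mutation", ncol(mut)),
             rep("cna_arm", if (is.null(cna_bin)) 0 else ncol(cna_bin)),
             rep("protein", if (is.null(protein)) 0 else ncol(protein)),
             rep("clinical", if (is.null(clinical)) 0 else ncol(clinical)))
  values <- do.call(cbind, Filter(Negate(is.null), blocks))
  if (is.null(values) || !ncol(values)) stop("no features survived the filters")
  fm <- feature_matrix(values, kinds)
  attr(fm, "dropped") <- unique(dropped)
  fm
}

build_mutation_matrix <- function(mutations) {
  if (is.data.frame(mutations) &&
      all(c("sample", "gene") %in% names(mutations))) {
    pc <- mutations$protein_change
    aa_change <- !is.na(pc) & nzchar(as.character(pc))
    calls <- mutations[aa_change, , drop = FALSE]
    samples <- sort(unique(as.character(mutations$sample)))
    genes <- sort(unique(as.character(mutations$gene)))
    m <- matrix(0, length(samples), length(genes),
                dimnames = list(samples, genes))
    if (nrow(calls)) {
      m[cbind(match(as.character(calls$sample), samples),
              match(as.character(calls$gene), genes))] <- 1
    }
    m
  } else {
    m <- as.matrix(mutations)
    storage.mode(m) <- "double"
    if (!all(m %in% c(0, 1))) stop("mutation matrix must be binary 0/1")
    m
  }
}
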