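# End-to-end orchestration: simulate -> prepare -> train/rank -> GSEA ->
# density -> associations -> survival, under one seeded configuration.

#' Pipeline run configuration
#'
#' Stage toggles plus the per-stage settings. The demo defaults simulate a
#' compact cohort so a full run finishes in minutes on one CPU; sizes are
#' stated in the methods vignette.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "prepare", "train", "rank", "gsea", "density", "assoc",
#'   "survive")`.
#' @param out_dir directory for stage outputs (created if needed).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param n_samples,n_features cohort dimensions for the simulate stage.
#' @param n_genes,planted_set_size,set_effect expression-model settings.
#' @param n_patterns number of nuclei point patterns (one per "slide").
#' @param training a [training_config()] for the genetic-protein model.
#' @param training_expr a [training_config()] for the transcriptional model.
#' @param prep a [feature_prep_config()].
#' @param n_splits Monte-Carlo CV splits.
#' @param gmt optional path to a GMT file; when `NULL`, random sets plus
#'   the planted set are generated.
#' @param n_sets,set_size random gene-set collection dimensions.
#' @param n_perm GSEA permutations.
#' @param features,outcomes,ce_labels,expression,patterns optional
#'   pre-loaded inputs used when `"simulate"` is not among the stages.
#' @return a `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "prepare", "train", "rank",
                                  "gsea", "density", "assoc", "survive"),
                       out_dir = tempfile("oligoprog_run_"),
                       seed = 1L,
                       n_samples = 169L, n_features = 50L,
                       n_genes = 2000L, planted_set_size = 50L,
                       set_effect = -0.5,
                       n_patterns = 20L,
                       training = training_config(),
                       training_expr = training_config(n_neurons = 500L),
                       prep = feature_prep_config(),
                       n_splits = 20L,
                       gmt = NULL, n_sets = 50L, set_size = 25L,
                       n_perm = 1000L,
                       features = NULL, outcomes = NULL, ce_labels = NULL,
                       expression = NULL, patterns = NULL) {
  known <- c("simulate", "prepare", "train", "rank", "gsea", "density",
             "assoc", "survive")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks sample-id alignment across tables, value ranges and gene-set
#' well-formedness; returns findings instead of raising.
#'
#' @param config a [run_config()] (with any pre-loaded inputs attached).
#' @return data frame of findings with columns `level` (`"error"` /
#'   `"warning"`), `stage` and `message`; zero rows means clean.
#' @export
validate_inputs <- function(config) {
  findings <- list()
  note <- function(level, stage, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, stage = stage, message = message,
      stringsAsFactors = FALSE)
  }
  if (!"simulate" %in% config$stages) {
    needs_cohort <- any(c("prepare", "train", "rank", "assoc", "survive")
                        %in% config$stages)
    if (needs_cohort && is.null(config$features)) {
      note("error", "prepare", "no features supplied and simulate disabled")
    }
    if (needs_cohort && is.null(config$outcomes)) {
      note("error", "train", "no outcomes supplied and simulate disabled")
    }
    if (!is.null(config$features) && !is.null(config$outcomes) &&
        !identical(rownames(config$features), config$outcomes$sample_id)) {
      note("error", "prepare",
           "sample ids of features and outcomes do not match")
    }
    if (!is.null(config$features)) {
      kinds <- feature_kinds(config$features)
      cna <- unclass_matrix(config$features)[, kinds == "cna_arm",
                                             drop = FALSE]
      if (length(cna) && any(cna < -1 | cna > 1)) {
        note("error", "prepare", "arm CNA fraction outside [-1, 1]")
      }
    }
    if (!is.null(config$ce_labels) &&
        !all(config$ce_labels %in% c(0, 1))) {
      note("error", "assoc", "contrast-enhancement labels must be binary")
    }
    if ("density" %in% config$stages && is.null(config$patterns)) {
      note("error", "density",
           "no point patterns supplied and simulate disabled")
    }
  }
  if (!is.null(config$gmt)) {
    ok <- tryCatch({ read_gmt(config$gmt); TRUE },
                   error = function(e) { note("error", "gsea",
                                              conditionMessage(e)); FALSE })
    invisible(ok)
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(level = character(), stage = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (prepare -> train ->
#' rank; gsea after the transcriptional model; density, associations and
#' survival independently); a stage failure halts its dependents while
#' independent stages still run. All artifacts are written under the run
#' directory and a machine-readable JSON report is produced.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: per-stage status, seeds, and headline
#'   outputs (top-ranked features, enriched sets by direction, density
#'   split counts, association table, survival fits).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- validate_inputs(config)
  if (any(findings$level == "error")) {
    stop("input validation failed:\n  ",
         paste(findings$message[findings$level == "error"],
               collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stats::setNames(derive_seeds(config$seed, 8L),
                           c("simulate", "prepare", "train", "rank", "gsea",
                             "density", "assoc", "survive"))
  report <- list(seed = config$seed, stage_seeds = as.list(seeds),
                 stages = list(), out_dir = config$out_dir,
                 version = as.character(utils::packageVersion("oligoprog")))
  status <- function(name, value) report$stages[[name]] <<- value
  enabled <- function(s) s %in% config$stages
  failed <- character(0)
  run_stage <- function(name, deps, expr) {
    if (!enabled(name)) { status(name, list(status = "disabled")); return(NULL) }
    if (any(deps %in% failed)) {
      status(name, list(status = "skipped",
                        reason = paste("failed dependency:",
                                       paste(intersect(deps, failed),
                                             collapse = ","))))
      failed <<- c(failed, name)
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      status(name, list(status = "failed", error = conditionMessage(e)))
      failed <<- c(failed, name)
      NULL
    })
  }

  features <- config$features; outcomes <- config$outcomes
  ce_labels <- config$ce_labels; expression <- config$expression
  expr_outcomes <- NULL; patterns <- config$patterns
  planted_set <- NULL

  run_stage("simulate", character(0), {
    cohort <- generate_cohort(simulation_config(
      n_samples = config$n_samples, n_features = config$n_features,
      seed = seeds[["simulate"]]))
    features <- cohort$features
    outcomes <- cohort$outcomes
    ce_labels <- cohort$ce_labels
    gene_names <- sprintf("G%04d", seq_len(config$n_genes))
    planted_set <- gene_names[seq_len(config$planted_set_size)]
    expr <- generate_expression(config$n_samples, config$n_genes,
                                planted_set, config$set_effect,
                                gene_names = gene_names,
                                seed = seeds[["simulate"]] + 1L)
    expression <- expr$expression
    expr_outcomes <- expr$outcomes
    pat_seeds <- derive_seeds(seeds[["simulate"]] + 2L, config$n_patterns)
    lam_t <- with_seed(seeds[["simulate"]] + 3L,
                       exp(runif(config$n_patterns, log(0.004), log(0.02))))
    patterns <- lapply(seq_len(config$n_patterns), function(i) {
      generate_point_pattern(lam_t[i], 0.002, 0.5, 1000, 1000,
                             seed = pat_seeds[i])
    })
    write_feature_matrix(features, file.path(config$out_dir, "features.tsv"))
    write_outcomes(outcomes, file.path(config$out_dir, "outcomes.tsv"))
    status("simulate", list(status = "ok", n_samples = nrow(features),
                            n_patterns = length(patterns)))
  })

  prepared <- NULL
  run_stage("prepare", "simulate", {
    freq <- colMeans(unclass_matrix(features))
    keep <- freq >= config$prep$min_frequency
    prepared <- feature_matrix(
      unclass_matrix(features)[, keep, drop = FALSE],
      feature_kinds(features)[keep])
    status("prepare", list(status = "ok", n_kept = sum(keep),
                           dropped = colnames(features)[!keep]))
  })

  cv <- NULL
  run_stage("train", c("simulate", "prepare"), {
    cv <- monte_carlo_cv(prepared, outcomes, config$training,
                          n_splits = config$n_splits,
                          seed = seeds[["train"]], keep_models = TRUE)
    status("train", list(status = "ok", median_cindex = cv$median,
                         sd_cindex = cv$sd, cindex = cv$cindex))
  })

  ranking <- NULL
  run_stage("rank", "train", {
    scores <- cv_prognostic_scores(cv, prepared)
    ranking <- rank_features(scores)
    write.table(ranking, file.path(config$out_dir, "ranked_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    status("rank", list(status = "ok",
                        top = head(ranking$feature, 10L)))
  })

  run_stage("gsea", "simulate", {
    cfg <- config$training_expr; cfg$seed <- seeds[["gsea"]]
    oc <- expr_outcomes %||% outcomes
    model <- train_risk_model(expression, oc, cfg)
    sens <- feature_sensitivity(model, expression)
    gene_scores <- stats::setNames(sens$score, sens$feature)
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else {
      gene_names <- colnames(expression)
      random_sets <- with_seed(seeds[["gsea"]] + 1L, {
        lapply(seq_len(config$n_sets), function(i)
          sample(gene_names, config$set_size))
      })
      names(random_sets) <- sprintf("RANDOM_SET_%02d",
                                    seq_len(config$n_sets))
      if (!is.null(planted_set)) {
        random_sets$PLANTED_PROGNOSTIC_SET <- planted_set
      }
      random_sets
    }
    res <- preranked_gsea(gene_scores, sets, n_perm = config$n_perm,
                          seed = seeds[["gsea"]] + 2L)
    rep2 <- two_direction_report(res)
    write.table(res[, names(res) != "leading_edge"],
                file.path(config$out_dir, "gsea.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    status("gsea", list(
      status = "ok",
      poor_prognosis = head(rep2$poor_prognosis$set, 5L),
      good_prognosis = head(rep2$good_prognosis$set, 5L),
      results = res))
  })

  density_class <- NULL
  run_stage("density", "simulate", {
    fits <- lapply(patterns, function(pp) {
      fit_poisson_mixture(nearest_neighbor_distances(pp))
    })
    density_class <- classify_cohort(
      vapply(fits, function(f) f$lambda_tumor, numeric(1)))
    write.table(density_class, file.path(config$out_dir, "density.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    status("density", list(status = "ok",
                           split = table(density_class$label)))
  })

  assoc <- NULL
  run_stage("assoc", c("simulate", "prepare"), {
    assoc <- association_screen(prepared, ce_labels)
    write.table(assoc, file.path(config$out_dir, "associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    status("assoc", list(status = "ok", top = head(assoc, 5L)))
  })

  run_stage("survive", "simulate", {
    km_ce <- km_estimate(outcomes, ifelse(ce_labels == 1, "CE+", "CE-"))
    lr_ce <- logrank_test(outcomes, ce_labels)
    status("survive", list(
      status = "ok",
      median_by_ce = km_ce$median_survival,
      logrank_ce_p = lr_ce$p_two_sided))
  })

  report$stages <- report$stages[intersect(
    c("simulate", "prepare", "train", "rank", "gsea", "density", "assoc",
      "survive"), names(report$stages))]
  class(report) <- "run_report"
  jsonlite::write_json(strip_for_json(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

strip_for_json <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_for_json)
  else if (is.table(x)) as.list(x)
  else x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-8s %s\n", nm, x$stages[[nm]]$status))
  }
  invisible(x)
}
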