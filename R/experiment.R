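#' Configuration of one simulation-evaluation scenario
#'
#' Bundles everything that determines a run: population layout, generating
#' parameters, grouping design, drop-out strategy, replicate count and the
#' master seed. Two built-in scales are provided: `"paper"` (11 generations
#' of 30 sires x 20 dams x litter 6, phenotypes from the last 5 generations,
#' 18,000 phenotyped animals) and `"reduced"` (6 generations of 10 sires x
#' 10 dams x litter 6, last 3 generations phenotyped, 1,800 animals), a
#' desk-scale profile with the same generating model.
#'
#' @param scenario `"individual"`, `"group3x4"`, `"group6x2"` or
#'   `"group1x12"`.
#' @param dropout `"none"`, `"random"` or `"phenotypic"`.
#' @param scale `"reduced"` or `"paper"`, presetting the population layout.
#' @param replicates number of replicates.
#' @param seed master seed; replicate k runs on `seed + k`.
#' @param dropout_proportion fraction of the phenotyped cohort dropped.
#' @param params generating [trait_params()].
#' @param times test time points.
#' @param order Legendre order of the simulated and fitted curves.
#' @param n_generations,n_sires,n_dams_per_sire,litter_size,phenotyped_generations
#'   population layout overrides (counts; `phenotyped_generations` = how many
#'   trailing generations carry records).
#' @param fit_options options passed to [estimate_vc()].
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("individual", "group3x4",
                                         "group6x2", "group1x12"),
                            dropout = c("none", "random", "phenotypic"),
                            scale = c("reduced", "paper"),
                            replicates = 10, seed = 1,
                            dropout_proportion = 0.15,
                            params = trait_params(), times = 1:6, order = 1,
                            n_generations = NULL, n_sires = NULL,
                            n_dams_per_sire = NULL, litter_size = NULL,
                            phenotyped_generations = NULL,
                            fit_options = list()) {
  scenario <- match.arg(scenario)
  dropout <- match.arg(dropout)
  scale <- match.arg(scale)
  layout <- if (scale == "paper")
    list(n_generations = 11, n_sires = 30, n_dams_per_sire = 20,
         litter_size = 6, phenotyped_generations = 5)
  else
    list(n_generations = 6, n_sires = 10, n_dams_per_sire = 10,
         litter_size = 6, phenotyped_generations = 3)
  ovr <- list(n_generations = n_generations, n_sires = n_sires,
              n_dams_per_sire = n_dams_per_sire, litter_size = litter_size,
              phenotyped_generations = phenotyped_generations)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) layout[[nm]] <- ovr[[nm]]
  structure(c(list(scenario = scenario, dropout = dropout, scale = scale,
                   replicates = replicates, seed = seed,
                   dropout_proportion = dropout_proportion,
                   params = params, times = times, order = order,
                   fit_options = fit_options), layout),
            class = "scenario_config")
}

## One full replicate: simulate, group, drop, fit, evaluate.
.run_replicate <- function(cfg, rep_seed) {
  L <- legendre_matrix(cfg$times, cfg$order)
  ped <- simulate_pedigree(cfg$n_generations, cfg$n_sires,
                           cfg$n_dams_per_sire, cfg$litter_size,
                           seed = rep_seed)
  F <- compute_inbreeding(ped)
  eff <- simulate_genetic_effects(ped, cfg$params$G, seed = rep_seed, F = F)
  gens <- sort(unique(ped$generation))
  ph_gens <- tail(gens, cfg$phenotyped_generations)
  phen <- simulate_pe_and_phenotypes(ped, eff, cfg$params, L,
                                     generations = ph_gens, seed = rep_seed)
  cohort_all <- unique(phen$id)
  plan <- switch(cfg$dropout,
    none = data.frame(id = integer(), drop_time = integer(),
                      strategy = character()),
    random = plan_dropout_random(cohort_all, cfg$dropout_proportion,
                                 nrow(L), seed = rep_seed),
    phenotypic = plan_dropout_phenotypic(phen, cohort_all,
                                         cfg$dropout_proportion, nrow(L),
                                         seed = rep_seed))
  phen <- apply_dropout(phen, plan)
  if (cfg$scenario == "individual") {
    design <- build_design(phen, ped, L)
  } else {
    pens <- do.call(rbind, lapply(seq_along(ph_gens), function(gi) {
      p <- assign_pens(ped, ph_gens[gi], cfg$scenario,
                       seed = rep_seed + 7919L * gi)
      p$pen <- p$pen + (gi - 1) * 100000L
      p
    }))
    groups <- aggregate_group_records(phen, pens)
    design <- build_design(groups, ped, L)
  }
  ainv <- a_inverse(ped, F)
  fit <- estimate_vc(design, ainv, options = cfg$fit_options)
  ebv <- ebv_table(fit$a_hat, eff, L)
  cohort <- unique(phen$id[phen$observed])
  met <- evaluate_ebv(ebv, cohort)
  c(as.list(fit$theta),
    list(r = met$r, b1 = met$b1, n_validated = met$n_animals,
         converged = fit$converged, iterations = fit$iterations,
         n_em_steps = fit$n_em_steps))
}

#' Run a replicated scenario
#'
#' Executes `cfg$replicates` independent replicates (replicate k seeded with
#' `cfg$seed + k`): simulate the population and phenotypes, form pens and
#' drop outs, estimate variance components by AI-REML, predict breeding
#' values by BLUP at the replicate's own estimates, and score accuracy and
#' bias of the whole-trajectory index. Failed replicates are recorded and
#' excluded from the summary with a warning.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `scenario_result` with `replicates` (one row per
#'   successful replicate), `summary` (mean and SD per quantity), `failures`
#'   and `config`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"), cfg$replicates >= 1)
  rows <- vector("list", cfg$replicates)
  failures <- character()
  for (k in seq_len(cfg$replicates)) {
    res <- tryCatch(.run_replicate(cfg, cfg$seed + k), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("replicate %d: %s", k, conditionMessage(res)))
    } else {
      rows[[k]] <- data.frame(replicate = k, res)
    }
  }
  reps <- do.call(rbind, rows)
  if (length(failures))
    warning("replicates failed and were excluded: ",
            paste(failures, collapse = "; "))
  if (is.null(reps)) stop("all replicates failed")
  structure(list(replicates = reps, summary = summarize_replicates(reps),
                 failures = failures, config = cfg),
            class = "scenario_result")
}

#' Mean and SD over replicates
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' numeric quantity over replicates, the format of the study's summary
#' tables. With a single replicate the SD is reported as 0 and flagged.
#'
#' @param reps `data.frame` of per-replicate results.
#' @return `data.frame` with columns `quantity`, `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(reps) {
  stopifnot(nrow(reps) >= 1)
  num <- vapply(reps, is.numeric, logical(1))
  num[names(num) %in% c("replicate")] <- FALSE
  qs <- names(reps)[num]
  out <- data.frame(
    quantity = qs,
    mean = vapply(qs, function(q) mean(reps[[q]]), numeric(1)),
    sd = vapply(qs, function(q)
      if (nrow(reps) > 1) sd(reps[[q]]) else 0, numeric(1)),
    n = nrow(reps)
  )
  rownames(out) <- NULL
  if (nrow(reps) == 1)
    attr(out, "single_replicate") <- TRUE
  out
}

#' @method print scenario_result
#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario %s / dropout %s (%s scale, %d replicates)\n",
              cfg$scenario, cfg$dropout, cfg$scale,
              nrow(x$replicates)))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}
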