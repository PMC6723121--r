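#' Allocate a generation's animals to pens of 12
#'
#' Implements the three grouping designs compared in the study, all producing
#' pens of 12 animals formed within one generation:
#' * `group3x4`: every litter of 6 is randomly split into two sub-litters of
#'   3; each pen combines 4 sub-litters from 4 different litters (medium
#'   within- and across-pen relationship).
#' * `group6x2`: each pen holds the complete litters of 2 distinct dams (high
#'   within-pen relationship).
#' * `group1x12`: each pen holds 12 animals from 12 distinct litters (low
#'   within-pen relationship).
#'
#' @param ped pedigree.
#' @param generation generation index whose animals are penned.
#' @param scenario one of `"group3x4"`, `"group6x2"`, `"group1x12"`.
#' @param seed integer seed (dedicated stream).
#' @return `data.frame` with one row per animal: `pen`, `generation`, `id`,
#'   `litter`. Pens partition the generation.
#' @export
assign_pens <- function(ped, generation,
                        scenario = c("group3x4", "group6x2", "group1x12"),
                        seed = 1) {
  scenario <- match.arg(scenario)
  gen <- ped[ped$generation == generation, ]
  if (nrow(gen) == 0) stop("no animals in generation ", generation)
  if (nrow(gen) %% 12 != 0)
    stop("infeasible design: generation size ", nrow(gen),
         " not divisible by 12")
  litters <- split(gen$id, gen$litter)
  if (any(lengths(litters) != 6))
    stop("infeasible design: pen scenarios require litters of size 6")
  n_pens <- nrow(gen) %/% 12
  .set_stage_seed(seed, "grouping")
  members <- switch(scenario,
    group3x4 = {
      ## split each litter into two random triples
      subs <- lapply(litters, function(ids) {
        ids <- sample(ids)
        list(ids[1:3], ids[4:6])
      })
      sub_litter <- rep(seq_along(litters), each = 2)
      subs <- unlist(subs, recursive = FALSE)
      .fill_pens(subs, sub_litter, n_pens, per_pen = 4,
                 label = "group3x4")
    },
    group6x2 = {
      if (length(litters) %% 2 != 0)
        stop("infeasible design: group6x2 needs an even number of litters")
      ord <- sample(length(litters))
      lapply(seq_len(n_pens), function(p)
        c(litters[[ord[2 * p - 1]]], litters[[ord[2 * p]]]))
    },
    group1x12 = {
      singles <- lapply(gen$id, identity)
      .fill_pens(singles, match(gen$litter, names(litters)), n_pens,
                 per_pen = 12, label = "group1x12")
    })
  out <- do.call(rbind, lapply(seq_along(members), function(p) {
    ids <- members[[p]]
    data.frame(pen = p, generation = generation, id = ids,
               litter = gen$litter[match(ids, gen$id)])
  }))
  rownames(out) <- NULL
  out
}

## Greedy constrained allocation: distribute `units` (vectors of animal ids,
## each tagged with a litter) over pens so that no pen receives two units
## from the same litter. Always taking litters with the most unplaced units
## first avoids end-game deadlocks; ties are broken at random.
.fill_pens <- function(units, unit_litter, n_pens, per_pen, label) {
  remaining <- split(seq_along(units), unit_litter)
  pens <- vector("list", n_pens)
  for (p in seq_len(n_pens)) {
    counts <- lengths(remaining)
    avail <- which(counts > 0)
    if (length(avail) < per_pen)
      stop("infeasible design: ", label, " needs ", per_pen,
           " distinct litters per pen, only ", length(avail), " left")
    ord <- avail[order(-counts[avail], runif(length(avail)))]
    take <- ord[seq_len(per_pen)]
    picked <- vapply(take, function(l) {
      u <- remaining[[l]]
      u <- if (length(u) == 1) u else sample(u, 1)
      u
    }, integer(1))
    for (j in seq_along(take))
      remaining[[take[j]]] <- setdiff(remaining[[take[j]]], picked[j])
    pens[[p]] <- unlist(units[picked], use.names = FALSE)
  }
  pens
}

#' Random drop-out plan
#'
#' Chooses `round(proportion * N)` animals uniformly without replacement and
#' assigns each a drop-out time sampled uniformly from `1..T`.
#'
#' @param cohort_ids ids of the phenotyped cohort.
#' @param proportion fraction of the cohort to drop, in `[0, 1)`.
#' @param T number of test time points.
#' @param seed integer seed (dedicated stream).
#' @return `data.frame` with columns `id`, `drop_time`, `strategy`.
#' @export
plan_dropout_random <- function(cohort_ids, proportion = 0.15, T = 6,
                                seed = 1) {
  if (proportion < 0 || proportion >= 1)
    stop("proportion must be in [0, 1)")
  .set_stage_seed(seed, "dropout")
  n_drop <- round(proportion * length(cohort_ids))
  if (n_drop == 0)
    return(data.frame(id = integer(), drop_time = integer(),
                      strategy = character()))
  ids <- sample(cohort_ids, n_drop)
  data.frame(id = ids,
             drop_time = sample.int(T, n_drop, replace = TRUE),
             strategy = "random")
}

#' Phenotype-dependent drop-out plan
#'
#' For each time point t = 1..T the number of drop outs is drawn from a
#' Poisson distribution with mean `proportion * N / T`; among the animals not
#' yet dropped, the ones with the lowest phenotype at t leave the test at
#' time t (mimicking culling of poor performers). Ties are broken by id.
#'
#' @param phen complete phenotype table (before any drop out).
#' @param cohort_ids ids eligible to drop.
#' @inheritParams plan_dropout_random
#' @return `data.frame` with columns `id`, `drop_time`, `strategy`.
#' @export
plan_dropout_phenotypic <- function(phen, cohort_ids, proportion = 0.15,
                                    T = 6, seed = 1) {
  if (proportion < 0 || proportion >= 1)
    stop("proportion must be in [0, 1)")
  sub <- phen[phen$id %in% cohort_ids & phen$observed, ]
  if (!all(table(sub$id) == T))
    stop("phenotypes must be complete for the cohort before planning drop out")
  .set_stage_seed(seed, "dropout")
  lambda <- proportion * length(cohort_ids) / T
  alive <- sort(unique(sub$id))
  drops <- list()
  for (t in seq_len(T)) {
    ct <- rpois(1, lambda)
    if (ct > length(alive)) {
      warning("drop-out count at time ", t, " truncated to remaining animals")
      ct <- length(alive)
    }
    if (ct == 0) next
    st <- sub[sub$time == t & sub$id %in% alive, ]
    ord <- st$id[order(st$value, st$id)]
    gone <- ord[seq_len(ct)]
    drops[[t]] <- data.frame(id = gone, drop_time = t,
                             strategy = "phenotypic")
    alive <- setdiff(alive, gone)
  }
  out <- do.call(rbind, drops)
  if (is.null(out))
    out <- data.frame(id = integer(), drop_time = integer(),
                      strategy = character())
  rownames(out) <- NULL
  out
}

#' Apply a drop-out plan to a phenotype table
#'
#' Marks the records of every dropped animal as missing from its drop-out
#' time point onward; earlier records are untouched, so missingness is
#' monotone within animal.
#'
#' @param phen phenotype table.
#' @param plan drop-out plan from [plan_dropout_random()] or
#'   [plan_dropout_phenotypic()].
#' @return the phenotype table with updated `observed` flags.
#' @export
apply_dropout <- function(phen, plan) {
  if (nrow(plan) == 0) return(phen)
  if (!all(plan$id %in% phen$id))
    stop("drop-out plan contains animals without phenotypes")
  dt <- plan$drop_time[match(phen$id, plan$id)]
  hit <- !is.na(dt) & phen$time >= dt
  phen$observed[hit] <- FALSE
  phen
}
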