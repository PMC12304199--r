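#' The model parameter set
#'
#' A parameter set is a validated list (class `abdo_params`) holding the
#' complete model configuration:
#'
#' * `cohorts`: data.frame `start_age` (55-81), `sex`, `weight`
#'   (weights sum to 1 over the full table);
#' * `age_range`: the eligibility window actually modelled in the basecase
#'   (default 55-74; weights are renormalised within the window);
#' * `diseases`: named list of per-disease blocks. Cancer blocks
#'   (`type = "cancer"`) carry incidence (age/sex table of annual preclinical
#'   onset rates), per-stage `dwell_time` (years), `current_stage_distribution`
#'   (stage shares at symptomatic diagnosis), per-stage scan `sensitivity`,
#'   organ `coverage` on the upper abdominal field of view, per-stage annual
#'   `cancer_mortality` after diagnosis, `pathway_id`, a `prevalence_multiplier`
#'   and a per-stage `cost_multiplier`. The AAA block (`type = "aaa"`) carries a
#'   direct screen-detectable prevalence table, size distribution
#'   (small 3.0-4.4, medium 4.5-5.4, large >= 5.5 cm), annual growth and
#'   size-specific rupture probabilities, elective/emergency repair
#'   parameters and surveillance costs;
#' * `secondary`: list of secondary-finding blocks (organ, category
#'   `serious`/`minor`/`false_positive`, prevalence table, pathway);
#' * `treatment_cost`: 4 (stage) x 2 (first year / subsequent years) GBP per
#'   year, shared across cancers; `utility_multiplier`: same shape;
#' * `cost_schedule`: the itemised screening cost build-up;
#' * `pathways`: named diagnostic pathways (resource, unit_cost, quantity);
#' * `other_cause_mortality`, `baseline_utilities`: age/sex tables;
#' * `settings`: discount rates, WTP, PSA size, horizon age, RNG seed,
#'   radiation-harm utility decrement, secondary-finding utility decrement;
#' * `modifiers`: structural scenario knobs (stage-shift attenuation,
#'   stage-IV share multiplier, screening-arm mortality multipliers);
#' * `psa_distributions`: named list of [distribution()] objects keyed by
#'   dotted parameter path (e.g. `diseases.kidney.dwell_time.2`).
#'
#' @name abdo_params
NULL

CANCER_ORGANS <- c("kidney", "liver", "stomach", "oesophagus", "pancreas",
                   "upper_urinary_tract", "colon", "adrenal", "gallbladder",
                   "lymphoma")
STAGES <- c("I", "II", "III", "IV")
AAA_SIZES <- c("small", "medium", "large")

new_parameter_set <- function(x) {
  structure(x, class = "abdo_params")
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities in \[0,1\], costs >= 0,
#' simplexes summing to 1, cohort weights summing to 1, pathway references
#' resolving, and settings consistency. Errors name the offending dotted path.
#'
#' @param params a parameter set (list or `abdo_params`).
#' @return the validated parameter set, invisibly classed `abdo_params`.
#' @export
validate_parameter_set <- function(params) {
  p <- params

  ## cohorts
  ch <- p$cohorts
  if (!is.data.frame(ch) || !all(c("start_age", "sex", "weight") %in% names(ch))) {
    abort_validation("cohorts", "must be a data.frame with start_age, sex, weight")
  }
  if (abs(sum(ch$weight) - 1) > 1e-9) abort_validation("cohorts.weight", "weights must sum to 1")
  check_prob(ch$weight, "cohorts.weight")
  if (any(ch$start_age < 55 | ch$start_age > 81)) {
    abort_validation("cohorts.start_age", "ages must lie in 55-81")
  }
  if (!all(ch$sex %in% c("male", "female"))) abort_validation("cohorts.sex", "sex must be male/female")

  ar <- p$age_range
  if (!(is.numeric(ar) && length(ar) == 2 && ar[1] <= ar[2])) {
    abort_validation("age_range", "must be c(lo, hi)")
  }

  ## settings
  s <- p$settings
  for (f in c("discount_rate_costs", "discount_rate_qalys")) {
    if (!is_scalar_number(s[[f]]) || s[[f]] < 0) abort_validation(paste0("settings.", f), "rate must be >= 0")
  }
  if (!is_scalar_number(s$wtp) || s$wtp <= 0) abort_validation("settings.wtp", "wtp must be > 0")
  if (!is_scalar_number(s$horizon_age) || s$horizon_age <= max(ch$start_age)) {
    abort_validation("settings.horizon_age", "horizon must exceed max cohort start age")
  }
  check_prob(s$radiation_decrement, "settings.radiation_decrement")
  check_prob(s$secondary_utility_decrement %||% 0, "settings.secondary_utility_decrement")

  ## age/sex tables
  for (nm in c("other_cause_mortality", "baseline_utilities")) {
    tb <- p[[nm]]
    if (!is.data.frame(tb)) abort_validation(nm, "must be a data.frame(age, sex, value)")
    check_prob(tb$value, paste0(nm, ".value"))
  }

  ## diseases
  if (!is.list(p$diseases) || length(p$diseases) == 0) abort_validation("diseases", "empty")
  for (nm in names(p$diseases)) {
    d <- p$diseases[[nm]]
    path <- function(f) paste0("diseases.", nm, ".", f)
    if (identical(d$type, "cancer")) {
      if (any(d$dwell_time <= 0) || length(d$dwell_time) != 4) {
        abort_validation(path("dwell_time"), "four positive dwell times required")
      }
      check_simplex(d$current_stage_distribution, path("current_stage_distribution"))
      if (length(d$sensitivity) != 4) abort_validation(path("sensitivity"), "four per-stage values required")
      check_prob(d$sensitivity, path("sensitivity"))
      check_prob(d$coverage, path("coverage"))
      check_prob(d$cancer_mortality, path("cancer_mortality"))
      check_nonneg(d$incidence$value, path("incidence.value"))
      check_nonneg(d$prevalence_multiplier, path("prevalence_multiplier"))
      check_nonneg(d$cost_multiplier, path("cost_multiplier"))
      if (!is.null(d$pathway_id) && is.null(p$pathways[[d$pathway_id]])) {
        abort_validation(path("pathway_id"), sprintf("pathway '%s' not defined", d$pathway_id))
      }
    } else if (identical(d$type, "aaa")) {
      check_prob(d$prevalence$value, path("prevalence.value"))
      check_simplex(d$size_distribution, path("size_distribution"))
      check_prob(d$growth, path("growth"))
      check_prob(d$rupture_rate, path("rupture_rate"))
      check_prob(d$elective_repair$operative_mortality, path("elective_repair.operative_mortality"))
      check_nonneg(d$elective_repair$cost, path("elective_repair.cost"))
      check_prob(d$emergency_repair$survival, path("emergency_repair.survival"))
      check_nonneg(d$emergency_repair$cost, path("emergency_repair.cost"))
      check_nonneg(d$surveillance_cost, path("surveillance_cost"))
      check_nonneg(d$prevalence_multiplier, path("prevalence_multiplier"))
      if (!is.null(d$pathway_id) && is.null(p$pathways[[d$pathway_id]])) {
        abort_validation(path("pathway_id"), sprintf("pathway '%s' not defined", d$pathway_id))
      }
    } else {
      abort_validation(paste0("diseases.", nm, ".type"), "must be 'cancer' or 'aaa'")
    }
  }

  ## secondary findings
  for (i in seq_along(p$secondary)) {
    b <- p$secondary[[i]]
    path <- function(f) sprintf("secondary.%s.%s", i, f)
    if (!b$category %in% c("serious", "minor", "false_positive")) {
      abort_validation(path("category"), "unknown category")
    }
    check_prob(b$prevalence$value, path("prevalence.value"))
    if (b$category != "minor" && is.null(p$pathways[[b$pathway_id]])) {
      abort_validation(path("pathway_id"), sprintf("pathway '%s' not defined", b$pathway_id))
    }
  }

  ## global reward tables
  check_nonneg(p$treatment_cost, "treatment_cost")
  if (!all(dim(p$treatment_cost) == c(4, 2))) abort_validation("treatment_cost", "must be 4x2")
  check_prob(p$utility_multiplier, "utility_multiplier")
  if (!all(dim(p$utility_multiplier) == c(4, 2))) abort_validation("utility_multiplier", "must be 4x2")

  ## screening cost schedule
  cs <- p$cost_schedule
  check_nonneg(cs$items$unit_cost, "cost_schedule.items.unit_cost")
  if (!all(cs$items$applies_to %in% c("negative", "positive", "both"))) {
    abort_validation("cost_schedule.items.applies_to", "must be negative/positive/both")
  }
  if (!is_scalar_number(cs$review_meeting_batch) || cs$review_meeting_batch < 1) {
    abort_validation("cost_schedule.review_meeting_batch", "batch must be >= 1")
  }

  ## pathways
  for (nm in names(p$pathways)) {
    pw <- p$pathways[[nm]]
    check_nonneg(pw$unit_cost, sprintf("pathways.%s.unit_cost", nm))
    check_nonneg(pw$quantity, sprintf("pathways.%s.quantity", nm))
  }

  ## modifiers
  m <- p$modifiers
  check_prob(m$stage_shift_attenuation, "modifiers.stage_shift_attenuation")
  check_nonneg(m$stage4_share_multiplier, "modifiers.stage4_share_multiplier")
  check_nonneg(m$screening_mortality_multiplier, "modifiers.screening_mortality_multiplier")

  ## PSA distributions
  for (nm in names(p$psa_distributions)) {
    validate_distribution(p$psa_distributions[[nm]], paste0("psa_distributions.", nm))
  }

  invisible(new_parameter_set(p))
}

## ------------------------------------------------------------------------
## dotted-path accessors ("diseases.kidney.dwell_time.2")

param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (k in keys) {
    idx <- suppressWarnings(as.integer(k))
    x <- if (!is.na(idx) && is.null(names(x))) x[[idx]]
         else if (!is.na(idx) && is.numeric(x)) x[[idx]]
         else x[[k]]
    if (is.null(x)) stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  x
}

param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    k <- keys[[1]]
    idx <- suppressWarnings(as.integer(k))
    key <- if (!is.na(idx) && (is.numeric(x) || is.null(names(x)))) idx else k
    if ((is.character(key) && is.null(x[[key]])) ||
        (is.numeric(key) && key > length(x))) {
      stop(sprintf("unknown parameter path segment '%s'", k), call. = FALSE)
    }
    if (length(keys) == 1) x[[key]] <- value
    else x[[key]] <- rec(x[[key]], keys[-1])
    x
  }
  out <- rec(unclass(params), keys)
  new_parameter_set(out)
}

## ------------------------------------------------------------------------
## serialisation: YAML manifest + CSV tables

#' Write a parameter set to disk
#'
#' Writes a `manifest.yaml` plus CSV tables (age/sex-indexed arrays, cost
#' schedule, diagnostic pathways, cohort weights) under `dir`. The same layout
#' is read back by [load_parameter_set()].
#'
#' @param params a validated parameter set.
#' @param dir output directory (created if absent).
#' @param force overwrite an existing bundle.
#' @return `dir`, invisibly.
#' @export
write_parameter_set <- function(params, dir, force = FALSE) {
  if (dir.exists(dir) && file.exists(file.path(dir, "manifest.yaml")) && !force) {
    stop(sprintf("'%s' already holds a parameter bundle (use force = TRUE)", dir),
         call. = FALSE)
  }
  tdir <- file.path(dir, "tables")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)

  wcsv <- function(df, name) utils::write.csv(df, file.path(tdir, name), row.names = FALSE)
  wcsv(params$cohorts, "cohorts.csv")
  wcsv(params$other_cause_mortality, "other_cause_mortality.csv")
  wcsv(params$baseline_utilities, "baseline_utilities.csv")

  inc <- do.call(rbind, lapply(names(params$diseases), function(nm) {
    d <- params$diseases[[nm]]
    if (d$type == "cancer") cbind(organ = nm, d$incidence)
    else cbind(organ = nm, d$prevalence)
  }))
  wcsv(inc, "incidence.csv")

  sec <- do.call(rbind, lapply(seq_along(params$secondary), function(i) {
    b <- params$secondary[[i]]
    cbind(organ = b$organ, category = b$category,
          pathway_id = b$pathway_id %||% "", b$prevalence)
  }))
  if (!is.null(sec)) wcsv(sec, "secondary_prevalence.csv")

  wcsv(params$cost_schedule$items, "cost_schedule.csv")
  pw <- do.call(rbind, lapply(names(params$pathways), function(nm) {
    cbind(pathway_id = nm, params$pathways[[nm]])
  }))
  if (!is.null(pw)) wcsv(pw, "pathways.csv")

  ## everything non-tabular into the manifest; table fields become markers so
  ## the loader can reinsert them at the same position (field-order-stable
  ## round trip)
  strip <- function(d) {
    for (f in c("incidence", "prevalence")) if (!is.null(d[[f]])) d[[f]] <- "@csv"
    d
  }
  manifest <- list(
    format = "abdoscreen-parameter-bundle-v1",
    age_range = as.numeric(params$age_range),
    settings = params$settings,
    modifiers = params$modifiers,
    review_meeting_batch = params$cost_schedule$review_meeting_batch,
    treatment_cost = as.numeric(params$treatment_cost),
    utility_multiplier = as.numeric(params$utility_multiplier),
    diseases = lapply(params$diseases, strip),
    psa_distributions = lapply(params$psa_distributions, function(d) {
      c(list(kind = d$kind), d$params)
    })
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"), precision = 15)
  invisible(dir)
}

#' Load a parameter set from a bundle directory
#'
#' Reads the `manifest.yaml` + CSV bundle written by [write_parameter_set()]
#' (or by the synthetic generator) and returns a fully validated parameter set.
#'
#' @param path bundle directory (or path to its `manifest.yaml`).
#' @return a validated `abdo_params` object.
#' @export
load_parameter_set <- function(path) {
  if (grepl("manifest\\.ya?ml$", path)) path <- dirname(path)
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) stop(sprintf("no manifest.yaml under '%s'", path), call. = FALSE)
  manifest <- yaml::read_yaml(mf)
  if (!identical(manifest$format, "abdoscreen-parameter-bundle-v1")) {
    stop("unrecognised parameter bundle format", call. = FALSE)
  }
  tdir <- file.path(path, "tables")
  rcsv <- function(name) utils::read.csv(file.path(tdir, name), stringsAsFactors = FALSE)

  inc <- rcsv("incidence.csv")
  diseases <- manifest$diseases
  for (nm in names(diseases)) {
    d <- diseases[[nm]]
    tab <- inc[inc$organ == nm, c("age", "sex", "value")]
    rownames(tab) <- NULL
    for (f in c("dwell_time", "current_stage_distribution", "sensitivity",
                "cancer_mortality", "cost_multiplier", "size_distribution",
                "growth", "rupture_rate", "surveillance_cost")) {
      if (!is.null(d[[f]])) d[[f]] <- as.numeric(d[[f]])
    }
    if (identical(d$type, "cancer")) d[["incidence"]] <- tab else d[["prevalence"]] <- tab
    diseases[[nm]] <- d
  }

  secondary <- list()
  spath <- file.path(tdir, "secondary_prevalence.csv")
  if (file.exists(spath)) {
    sec <- utils::read.csv(spath, stringsAsFactors = FALSE)
    for (key in unique(paste(sec$organ, sec$category))) {
      sub <- sec[paste(sec$organ, sec$category) == key, ]
      secondary[[length(secondary) + 1]] <- list(
        organ = sub$organ[1], category = sub$category[1],
        pathway_id = if (nzchar(sub$pathway_id[1])) sub$pathway_id[1] else NULL,
        prevalence = { tb <- sub[, c("age", "sex", "value")]; rownames(tb) <- NULL; tb }
      )
    }
  }

  pathways <- list()
  ppath <- file.path(tdir, "pathways.csv")
  if (file.exists(ppath)) {
    pw <- utils::read.csv(ppath, stringsAsFactors = FALSE)
    for (nm in unique(pw$pathway_id)) {
      tb <- pw[pw$pathway_id == nm, c("resource", "unit_cost", "quantity")]
      rownames(tb) <- NULL
      pathways[[nm]] <- tb
    }
  }

  params <- new_parameter_set(list(
    cohorts = rcsv("cohorts.csv"),
    age_range = as.numeric(manifest$age_range),
    diseases = diseases,
    secondary = secondary,
    treatment_cost = matrix(as.numeric(manifest$treatment_cost), 4, 2,
                            dimnames = list(STAGES, c("year1", "later"))),
    utility_multiplier = matrix(as.numeric(manifest$utility_multiplier), 4, 2,
                                dimnames = list(STAGES, c("year1", "later"))),
    cost_schedule = list(items = rcsv("cost_schedule.csv"),
                         review_meeting_batch = manifest$review_meeting_batch),
    pathways = pathways,
    other_cause_mortality = rcsv("other_cause_mortality.csv"),
    baseline_utilities = rcsv("baseline_utilities.csv"),
    settings = manifest$settings,
    modifiers = lapply(manifest$modifiers, as.numeric),
    psa_distributions = lapply(manifest$psa_distributions, function(d) {
      do.call(distribution, c(list(kind = d$kind),
                              lapply(d[setdiff(names(d), "kind")], as.numeric)))
    })
  ))
  validate_parameter_set(params)
  params
}

## ------------------------------------------------------------------------
## scenarios

#' Define a scenario
#'
#' A scenario is a named set of modifiers applied on top of a base parameter
#' set by [apply_scenario()]. Recognised modifiers:
#' `discount_rate` (scalar, applied to costs and QALYs),
#' `prevalence_multiplier` (named vector by disease),
#' `stage4_cost_multiplier` / `all_stage_cost_multiplier` (named vector by
#' disease, `".all"` applying to every cancer),
#' `mortality_multiplier_screening` (length-4 per-stage vector),
#' `stage_shift_attenuation` (0 = full screen stage shift, 1 = none),
#' `stage4_share_multiplier` (scales the stage-IV share at screen),
#' `secondary_utility_decrement` (one-off QALY loss per secondary finding),
#' `age_range` (c(lo, hi) cohort window), `include_organs` (character mask of
#' organs retained in the model).
#'
#' @param name scenario label.
#' @param ... modifiers (see Details).
#' @return an object of class `abdo_scenario`.
#' @export
scenario <- function(name, ...) {
  structure(list(name = name, modifiers = list(...)), class = "abdo_scenario")
}

#' Apply a scenario to a parameter set
#'
#' Pure transformation: returns a new parameter set, leaving `base` unchanged.
#' Unknown modifier names, or multipliers naming diseases absent from the base
#' set, raise an error naming the offender.
#'
#' @param base a validated parameter set.
#' @param scn an [scenario()] object.
#' @return a new validated `abdo_params`.
#' @export
apply_scenario <- function(base, scn) {
  stopifnot(inherits(scn, "abdo_scenario"))
  p <- unclass(base)
  known <- c("discount_rate", "prevalence_multiplier", "stage4_cost_multiplier",
             "all_stage_cost_multiplier", "mortality_multiplier_screening",
             "stage_shift_attenuation", "stage4_share_multiplier",
             "secondary_utility_decrement", "age_range", "include_organs",
             "radiation_decrement")
  unknown <- setdiff(names(scn$modifiers), known)
  if (length(unknown)) {
    stop(sprintf("unknown scenario modifier(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  m <- scn$modifiers

  if (!is.null(m$discount_rate)) {
    p$settings$discount_rate_costs <- m$discount_rate
    p$settings$discount_rate_qalys <- m$discount_rate
  }
  if (!is.null(m$radiation_decrement)) p$settings$radiation_decrement <- m$radiation_decrement
  if (!is.null(m$secondary_utility_decrement)) {
    p$settings$secondary_utility_decrement <- m$secondary_utility_decrement
  }
  if (!is.null(m$prevalence_multiplier)) {
    for (nm in names(m$prevalence_multiplier)) {
      if (nm == ".all") {
        for (dn in names(p$diseases)) {
          if (p$diseases[[dn]]$type == "cancer") {
            p$diseases[[dn]]$prevalence_multiplier <-
              p$diseases[[dn]]$prevalence_multiplier * m$prevalence_multiplier[[nm]]
          }
        }
      } else {
        if (is.null(p$diseases[[nm]])) {
          stop(sprintf("prevalence_multiplier targets unknown disease '%s'", nm), call. = FALSE)
        }
        p$diseases[[nm]]$prevalence_multiplier <-
          p$diseases[[nm]]$prevalence_multiplier * m$prevalence_multiplier[[nm]]
      }
    }
  }
  mult_costs <- function(p, named, stages) {
    for (nm in names(named)) {
      targets <- if (nm == ".all") {
        names(p$diseases)[vapply(p$diseases, function(d) d$type == "cancer", logical(1))]
      } else nm
      extra <- setdiff(targets, names(p$diseases))
      if (length(extra)) stop(sprintf("cost multiplier targets unknown disease '%s'", extra[1]), call. = FALSE)
      for (dn in targets) {
        p$diseases[[dn]]$cost_multiplier[stages] <-
          p$diseases[[dn]]$cost_multiplier[stages] * named[[nm]]
      }
    }
    p
  }
  if (!is.null(m$stage4_cost_multiplier)) p <- mult_costs(p, m$stage4_cost_multiplier, 4)
  if (!is.null(m$all_stage_cost_multiplier)) p <- mult_costs(p, m$all_stage_cost_multiplier, 1:4)
  if (!is.null(m$mortality_multiplier_screening)) {
    p$modifiers$screening_mortality_multiplier <- rep_len(m$mortality_multiplier_screening, 4)
  }
  if (!is.null(m$stage_shift_attenuation)) p$modifiers$stage_shift_attenuation <- m$stage_shift_attenuation
  if (!is.null(m$stage4_share_multiplier)) p$modifiers$stage4_share_multiplier <- m$stage4_share_multiplier
  if (!is.null(m$age_range)) p$age_range <- m$age_range
  if (!is.null(m$include_organs)) {
    keep_d <- names(p$diseases)[names(p$diseases) %in% m$include_organs]
    if (!length(keep_d) && !any(vapply(p$secondary, function(b) b$organ %in% m$include_organs, logical(1)))) {
      stop("include_organs mask leaves no modelled disease", call. = FALSE)
    }
    dropped <- setdiff(names(p$diseases), keep_d)
    p$diseases <- p$diseases[keep_d]
    p$secondary <- Filter(function(b) b$organ %in% m$include_organs, p$secondary)
    if (length(dropped) && length(p$psa_distributions)) {
      gone <- Reduce(`|`, lapply(paste0("diseases.", dropped, "."),
                                 function(pre) startsWith(names(p$psa_distributions), pre)))
      p$psa_distributions <- p$psa_distributions[!gone]
    }
  }
  validate_parameter_set(p)
}

## ------------------------------------------------------------------------
## PSA draws

## classify a path so distribution kinds can be sanity-checked against it
psa_target_check <- function(params, path, d) {
  cur <- param_get(params, path)
  if (d$kind == "dirichlet") {
    if (length(cur) != length(d$params$alpha) || abs(sum(cur) - 1) > 1e-6) {
      stop(sprintf("dirichlet distribution on '%s' requires a simplex target", path), call. = FALSE)
    }
  } else if (length(cur) != 1) {
    stop(sprintf("scalar distribution on vector-valued path '%s'", path), call. = FALSE)
  } else if (d$kind == "beta" && (cur < 0 || cur > 1)) {
    stop(sprintf("beta distribution on non-probability parameter '%s'", path), call. = FALSE)
  }
  invisible(TRUE)
}

## one realised parameter set + the sampled values; RNG state is the caller's
draw_parameter_set <- function(base, check = FALSE) {
  dists <- base$psa_distributions
  p <- base
  theta <- numeric(0)
  for (path in names(dists)) {
    d <- dists[[path]]
    if (check) psa_target_check(base, path, d)
    v <- draw_distribution(d)
    p <- param_set(p, path, v)
    if (d$kind == "dirichlet") {
      names(v) <- paste0(path, ".", seq_along(v))
      theta <- c(theta, v)
    } else {
      theta <- c(theta, stats::setNames(v, path))
    }
  }
  list(params = p, theta = theta)
}

psa_seed <- function(seed, i, attempt = 0L) {
  (as.integer(seed) + 7919L * as.integer(i) + as.integer(attempt)) %% .Machine$integer.max
}

#' Sample realised parameter sets for probabilistic analysis
#'
#' Draws `n` parameter sets from the distributions in
#' `base$psa_distributions`; parameters without a distribution keep their
#' fixed value. Draws are reproducible given `seed`; dirichlet-drawn stage
#' distributions remain on the simplex by construction.
#'
#' @param base a validated parameter set.
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @return list of `n` realised `abdo_params` objects.
#' @export
sample_psa_draws <- function(base, n, seed) {
  stopifnot(n >= 1)
  for (path in names(base$psa_distributions)) {
    psa_target_check(base, path, base$psa_distributions[[path]])
  }
  lapply(seq_len(n), function(i) {
    set.seed(psa_seed(seed, i))
    draw_parameter_set(base)$params
  })
}
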