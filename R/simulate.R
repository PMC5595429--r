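#' Simulation configuration for a patient/control recognition cohort
#'
#' Bundles the task design constants, the group sizes, and the latent
#' parameter distributions of the two-process generative model from which
#' trial-level data are simulated. The default design mirrors the study
#' setup: ROC task with 120 targets and 60 distractors rated on a 6-point
#' confidence scale; associative-pairs (PDP) task with 40 intact, 40
#' recombined and 40 new pairs; Remember/Know/Guess task with 60 targets
#' and 60 distractors; 12 patients (7 labelled dMTT, 5 iMTT) and 25
#' controls.
#'
#' The default group distributions encode the study's headline pattern:
#' patients have reduced recollection probability (`rho`) with familiarity
#' strength (`delta`) matched to controls. Subgroup-specific distributions
#' (dMTT: recollection and familiarity both lowered; iMTT: recollection
#' lowered less) are used by [draw_subject()] when asked for those groups,
#' and by [simulate_cohort()] only when `subgroup_effects = TRUE`; by
#' default the cohort's subgroup labels are metadata and all patients are
#' drawn from the common patient distribution.
#'
#' @param n_patients,n_controls Group sizes (defaults 12 and 25).
#' @param n_dmtt Number of patients labelled dMTT (default 7; the rest are
#'   iMTT).
#' @param seed Integer RNG seed used by [simulate_cohort()].
#' @param groups Named list of latent distributions per group; see
#'   [draw_subject()]. Defaults from `default_group_params()`.
#' @param design Task design constants (item counts per class).
#' @param subgroup_effects If `TRUE`, cohort patients are drawn from the
#'   dMTT/iMTT-specific distributions instead of the common patient one.
#' @param delta_assoc_frac Fraction of `delta` carried by recombined pairs'
#'   familiarity (default 1: pair components were studied, so recombined
#'   pairs feel as familiar as intact ones).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 12L, n_controls = 25L, n_dmtt = 7L,
                       seed = 1L,
                       groups = default_group_params(),
                       design = list(
                         roc = c(targets = 120L, distractors = 60L),
                         pdp = c(intact = 40L, recombined = 40L, new = 40L),
                         rkg = c(targets = 60L, distractors = 60L)
                       ),
                       subgroup_effects = FALSE,
                       delta_assoc_frac = 1) {
  stopifnot(n_patients >= 0, n_controls >= 0, n_dmtt >= 0,
            n_dmtt <= n_patients,
            delta_assoc_frac >= 0, delta_assoc_frac <= 1)
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         n_dmtt = as.integer(n_dmtt),
         seed = as.integer(seed), groups = groups, design = design,
         subgroup_effects = isTRUE(subgroup_effects),
         delta_assoc_frac = delta_assoc_frac),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_group_params <- function() {
  base <- list(
    rho_mean = 0.55, rho_sd = 0.12,
    delta_mean = 1.2, delta_sd = 0.30,
    criteria = c(-0.8, -0.35, 0.1, 0.55, 1.1), criteria_shift_sd = 0.15,
    yes_criterion_mean = 0.55, yes_criterion_sd = 0.15,
    guess_rate = 0.15
  )
  patient <- base
  patient$rho_mean <- 0.15
  dmtt <- patient
  dmtt$rho_mean <- 0.10
  dmtt$delta_mean <- 0.8
  imtt <- patient
  imtt$rho_mean <- 0.22
  list(control = base, patient = patient,
       patient_dMTT = dmtt, patient_iMTT = imtt)
}

#' Draw one subject's latent parameters
#'
#' Samples a subject's latents from the configured distribution of the
#' requested group: recollection probability `rho` (normal on the
#' probability scale, truncated to \[0, 1\]), familiarity strength `delta`
#' (normal, truncated at 0), the five ROC confidence criteria (the
#' configured template shifted by a normal subject offset), the yes/no
#' criterion used in the PDP and RKG tasks, and the guess rate. Uses the
#' current RNG state; seed externally (or via [simulate_cohort()]) for
#' reproducibility.
#'
#' @param group One of `"control"`, `"patient"`, `"patient_dMTT"`,
#'   `"patient_iMTT"`.
#' @param config A [sim_config()].
#' @return A list of class `"subject_latents"`: `rho`, `delta`,
#'   `criteria_roc`, `yes_criterion`, `guess_rate`, `group`.
#' @export
draw_subject <- function(group, config = sim_config()) {
  if (!group %in% names(config$groups))
    stop("unknown group label: ", group)
  g <- config$groups[[group]]
  rho <- min(1, max(0, stats::rnorm(1, g$rho_mean, g$rho_sd)))
  delta <- max(0, stats::rnorm(1, g$delta_mean, g$delta_sd))
  shift <- stats::rnorm(1, 0, g$criteria_shift_sd)
  structure(
    list(rho = rho, delta = delta,
         criteria_roc = g$criteria + shift,
         yes_criterion = stats::rnorm(1, g$yes_criterion_mean,
                                      g$yes_criterion_sd),
         guess_rate = g$guess_rate,
         group = group),
    class = "subject_latents"
  )
}

#' Simulate confidence-ROC task trials for one subject
#'
#' Generates one trial row per item under the dual-process model: each
#' target is recollected with probability `rho` (confidence 6, response
#' "yes"); otherwise its familiarity strength is Normal(`delta`, 1) and is
#' binned by the subject's five confidence criteria. Distractor strengths
#' are Normal(0, 1). Responses with confidence >= 4 are "yes". Targets
#' alternate deep/shallow encoding labels (the design manipulates depth;
#' scoring collapses across it).
#'
#' @param latents A [draw_subject()] result.
#' @param config A [sim_config()] (item counts come from `config$design`).
#' @param subject_id,group Identifier columns copied into every row.
#' @return Data frame of trial records (see [read_trials()] for the
#'   column contract).
#' @export
simulate_roc_trials <- function(latents, config = sim_config(),
                                subject_id = "s1", group = latents$group) {
  n_t <- config$design$roc[["targets"]]
  n_d <- config$design$roc[["distractors"]]
  crit <- latents$criteria_roc

  rec <- stats::runif(n_t) < latents$rho
  strength_t <- stats::rnorm(n_t, latents$delta, 1)
  conf_t <- findInterval(strength_t, crit) + 1L
  conf_t[rec] <- 6L
  conf_d <- findInterval(stats::rnorm(n_d, 0, 1), crit) + 1L

  depth <- rep(c("deep", "shallow"), length.out = n_t)
  data.frame(
    subject_id = subject_id, group = group, task = "ROC",
    item_class = rep(c("target", "distractor"), c(n_t, n_d)),
    response = ifelse(c(conf_t, conf_d) >= 4L, "yes", "no"),
    confidence = c(conf_t, conf_d),
    attribution = NA_character_,
    encoding_depth = c(depth, rep(NA_character_, n_d)),
    stringsAsFactors = FALSE
  )
}

#' Simulate associative-pairs (PDP) task trials for one subject
#'
#' Intact pairs are accepted with probability
#' \eqn{\rho + (1 - \rho)\,\Phi(\delta - c_{yes})} (recollection or
#' familiarity), recombined pairs with probability
#' \eqn{(1 - \rho)\,\Phi(\delta_{assoc} - c_{yes})} — recollection of the
#' original pairing vetoes acceptance — and new pairs with probability
#' \eqn{\Phi(-c_{yes})}. `delta_assoc` is `delta_assoc_frac * delta`.
#'
#' @inheritParams simulate_roc_trials
#' @return Data frame of trial records.
#' @export
simulate_pdp_trials <- function(latents, config = sim_config(),
                                subject_id = "s1", group = latents$group) {
  d <- config$design$pdp
  yc <- latents$yes_criterion
  d_assoc <- config$delta_assoc_frac * latents$delta
  p_yes <- c(
    intact = latents$rho + (1 - latents$rho) * stats::pnorm(latents$delta - yc),
    recombined = (1 - latents$rho) * stats::pnorm(d_assoc - yc),
    new = stats::pnorm(-yc)
  )
  cls <- rep(c("intact", "recombined", "new"),
             c(d[["intact"]], d[["recombined"]], d[["new"]]))
  yes <- stats::runif(length(cls)) < p_yes[cls]
  data.frame(
    subject_id = subject_id, group = group, task = "PDP",
    item_class = cls,
    response = ifelse(yes, "yes", "no"),
    confidence = NA_integer_,
    attribution = NA_character_,
    encoding_depth = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Simulate Remember/Know/Guess task trials for one subject
#'
#' Each target is recollected with probability `rho` ("yes" with
#' attribution R); otherwise, and for all distractors, familiarity strength
#' Normal(`delta`, 1) (distractors: `delta = 0`) is compared with the
#' subject's yes criterion. Supra-criterion items are "yes" with
#' attribution G with probability `guess_rate`, K otherwise; recollection
#' of unstudied items does not occur in this threshold model, so distractor
#' R responses have probability 0.
#'
#' @inheritParams simulate_roc_trials
#' @return Data frame of trial records.
#' @export
simulate_rkg_trials <- function(latents, config = sim_config(),
                                subject_id = "s1", group = latents$group) {
  n_t <- config$design$rkg[["targets"]]
  n_d <- config$design$rkg[["distractors"]]
  yc <- latents$yes_criterion

  sim_class <- function(n, mu, rho) {
    rec <- stats::runif(n) < rho
    fam_yes <- stats::rnorm(n, mu, 1) > yc
    yes <- rec | fam_yes
    attr_out <- rep(NA_character_, n)
    guess <- stats::runif(n) < latents$guess_rate
    attr_out[yes] <- ifelse(guess[yes], "G", "K")
    attr_out[rec] <- "R"
    list(yes = yes, attribution = attr_out)
  }
  tg <- sim_class(n_t, latents$delta, latents$rho)
  ds <- sim_class(n_d, 0, 0)

  data.frame(
    subject_id = subject_id, group = group, task = "RKG",
    item_class = rep(c("target", "distractor"), c(n_t, n_d)),
    response = ifelse(c(tg$yes, ds$yes), "yes", "no"),
    confidence = NA_integer_,
    attribution = c(tg$attribution, ds$attribution),
    encoding_depth = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete patient/control cohort
#'
#' Seeds the RNG from `config$seed`, draws every subject's latents and
#' simulates all three tasks per subject. Patients carry dMTT/iMTT
#' subgroup labels (`config$n_dmtt` of them dMTT); unless
#' `config$subgroup_effects` is `TRUE` all patients are drawn from the
#' common patient distribution, so by default the cohort has reduced
#' recollection with matched familiarity and the subgroup labels are pure
#' metadata. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_cohort"` with `trials` (one data frame of
#'   all trial records), `groups` (subject sheet: `subject_id`, `group`,
#'   `subgroup`), and `latents` (true per-subject parameters, for
#'   parameter-recovery studies).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  ids <- c(sprintf("p%02d", seq_len(config$n_patients)),
           sprintf("c%02d", seq_len(config$n_controls)))
  grp <- rep(c("patient", "control"),
             c(config$n_patients, config$n_controls))
  sub <- c(rep(c("dMTT", "iMTT"),
               c(config$n_dmtt, config$n_patients - config$n_dmtt)),
           rep("", config$n_controls))

  trial_list <- vector("list", length(ids))
  lat_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    draw_from <- if (grp[i] == "control") {
      "control"
    } else if (config$subgroup_effects) {
      paste0("patient_", sub[i])
    } else {
      "patient"
    }
    lat <- draw_subject(draw_from, config)
    trial_list[[i]] <- rbind(
      simulate_roc_trials(lat, config, ids[i], grp[i]),
      simulate_pdp_trials(lat, config, ids[i], grp[i]),
      simulate_rkg_trials(lat, config, ids[i], grp[i])
    )
    lat_rows[[i]] <- data.frame(
      subject_id = ids[i], group = grp[i], subgroup = sub[i],
      rho = lat$rho, delta = lat$delta,
      yes_criterion = lat$yes_criterion,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(trials = do.call(rbind, trial_list),
         groups = data.frame(subject_id = ids, group = grp, subgroup = sub,
                             stringsAsFactors = FALSE),
         latents = do.call(rbind, lat_rows)),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated recognition cohort:",
      sum(x$groups$group == "patient"), "patients,",
      sum(x$groups$group == "control"), "controls,",
      nrow(x$trials), "trials\n")
  invisible(x)
}
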