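#' Score every subject on every task
#'
#' Aggregates trial-level records into per-subject, per-task counts and
#' dispatches to the matching estimator: [fit_dpsd()] for the
#' confidence-ROC task, [pdp_indices()] for the associative-pairs task,
#' [rkg_indices()] for Remember/Know/Guess. Every task also gets overall
#' d' and criterion c (for the ROC task from the yes/no collapse,
#' confidence >= 4 vs <= 3). A subject x task cell with an empty item
#' class is dropped with a message; unknown task labels are an error.
#'
#' @param trials Data frame of trial records ([read_trials()] contract).
#' @param roc_method Passed to [fit_dpsd()] (`"ml"` or `"sse"`).
#' @param correct_rates Passed to [pdp_indices()].
#' @param rkg_variant Passed to [rkg_indices()].
#' @param pdp_fa_class Passed to [pdp_indices()] (`fa_class`).
#' @return Data frame with one row per subject x task: `subject_id`,
#'   `task`, `d_prime`, `criterion_c`, `R_index`, `F_index`, `hit_rate`,
#'   `fa_rate`, `converged` (ROC fits only, else `NA`).
#' @export
score_subjects <- function(trials, roc_method = "ml", correct_rates = TRUE,
                           rkg_variant = "irk", pdp_fa_class = "new") {
  req <- c("subject_id", "task", "item_class", "response")
  if (!all(req %in% names(trials)))
    stop("'trials' must have columns ", paste(req, collapse = ", "))
  bad <- setdiff(unique(trials$task), c("ROC", "PDP", "RKG"))
  if (length(bad))
    stop("unknown task label(s): ", paste(bad, collapse = ", "))

  cells <- unique(trials[c("subject_id", "task")])
  cells <- cells[order(cells$subject_id, cells$task), ]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sid <- cells$subject_id[i]
    tk <- cells$task[i]
    tr <- trials[trials$subject_id == sid & trials$task == tk, ]
    res <- switch(tk,
      ROC = score_roc_cell(tr, roc_method),
      PDP = score_pdp_cell(tr, correct_rates, pdp_fa_class),
      RKG = score_rkg_cell(tr, rkg_variant)
    )
    if (is.null(res)) {
      message("dropping ", sid, " x ", tk, ": empty item class")
      next
    }
    rows[[i]] <- cbind(data.frame(subject_id = sid, task = tk,
                                  stringsAsFactors = FALSE), res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

score_roc_cell <- function(tr, roc_method) {
  old <- tr[tr$item_class == "target", ]
  new <- tr[tr$item_class == "distractor", ]
  if (nrow(old) == 0 || nrow(new) == 0) return(NULL)
  old_counts <- tabulate(old$confidence, nbins = 6L)
  new_counts <- tabulate(new$confidence, nbins = 6L)
  fit <- fit_dpsd(old_counts, new_counts, method = roc_method)
  sdt <- dprime_c(sum(old_counts[4:6]), nrow(old),
                  sum(new_counts[4:6]), nrow(new))
  data.frame(d_prime = sdt$d_prime, criterion_c = sdt$criterion_c,
             R_index = fit$R, F_index = fit$d_f,
             hit_rate = sdt$hit_rate, fa_rate = sdt$fa_rate,
             converged = fit$converged)
}

score_pdp_cell <- function(tr, correct_rates, pdp_fa_class) {
  n <- table(factor(tr$item_class, levels = c("intact", "recombined", "new")))
  if (any(n == 0)) return(NULL)
  yes <- tapply(tr$response == "yes",
                factor(tr$item_class,
                       levels = c("intact", "recombined", "new")), sum)
  idx <- pdp_indices(yes[["intact"]], yes[["recombined"]], yes[["new"]],
                     n[["intact"]], n[["recombined"]], n[["new"]],
                     correct_rates = correct_rates, fa_class = pdp_fa_class)
  data.frame(d_prime = idx$d_prime, criterion_c = idx$criterion_c,
             R_index = idx$R_pdp, F_index = idx$F_pdp,
             hit_rate = idx$hit_rate, fa_rate = idx$fa_rate,
             converged = NA)
}

score_rkg_cell <- function(tr, rkg_variant) {
  count_row <- function(d) {
    yes <- d$response == "yes"
    c(R = sum(yes & d$attribution %in% "R"),
      K = sum(yes & d$attribution %in% "K"),
      G = sum(yes & d$attribution %in% "G"),
      no = sum(!yes))
  }
  old <- tr[tr$item_class == "target", ]
  new <- tr[tr$item_class == "distractor", ]
  if (nrow(old) == 0 || nrow(new) == 0) return(NULL)
  idx <- rkg_indices(count_row(old), count_row(new), variant = rkg_variant)
  data.frame(d_prime = idx$d_prime, criterion_c = idx$criterion_c,
             R_index = idx$R_rkg, F_index = idx$F_rkg,
             hit_rate = idx$yes_rate_old, fa_rate = idx$yes_rate_new,
             converged = NA)
}

#' Full group analysis of per-subject indices
#'
#' Runs the study's comparison battery on a scored cohort:
#' patient-vs-control Mann-Whitney tests (with the A effect size) for d',
#' R and F in each task; the same on the cross-task z summaries
#' ([z_summary()]); the zR-zF Spearman correlation within each group; and,
#' when subgroup labels are present, permutation tests (dMTT vs iMTT and
#' each subgroup vs controls) on the z summaries. Mann-Whitney comparisons
#' are oriented controls-vs-patients, so `effect_A` is the probability
#' that a random control outscores a random patient. Holm adjustment is
#' applied within each family: by default the three per-task comparisons
#' of one index form a family, and the three z-summary comparisons form
#' one.
#'
#' @param indices Output of [score_subjects()].
#' @param groups Data frame `subject_id`, `group` (`"patient"` /
#'   `"control"`), optional `subgroup` (`"dMTT"`, `"iMTT"` or `""`). Every
#'   subject in `indices` must appear here.
#' @param n_perm Monte Carlo permutations when exhaustive enumeration is
#'   infeasible.
#' @param seed Seed for Monte Carlo permutation p-values.
#' @return A list of class `"recmem_results"`: `per_task` (comparison
#'   table), `z_comparisons`, `z_table` (per-subject summaries),
#'   `correlations`, `subgroup` (permutation contrasts or `NULL`),
#'   `excluded` (subjects missing a task).
#' @export
run_group_analysis <- function(indices, groups, n_perm = 10000L, seed = 1L) {
  if (!all(c("subject_id", "group") %in% names(groups)))
    stop("'groups' must have columns subject_id and group")
  unlabeled <- setdiff(unique(indices$subject_id), groups$subject_id)
  if (length(unlabeled))
    stop("subject id(s) missing from the groups sheet: ",
         paste(unlabeled, collapse = ", "))
  control_ids <- groups$subject_id[groups$group == "control"]
  patient_ids <- groups$subject_id[groups$group == "patient"]

  pick <- function(tab, col, ids, task = NULL) {
    keep <- tab$subject_id %in% ids
    if (!is.null(task)) keep <- keep & tab$task == task
    tab[[col]][keep]
  }

  # per-task Mann-Whitney battery, Holm within each index family
  per_task <- NULL
  idx_cols <- c(d_prime = "d_prime", R = "R_index", F = "F_index")
  can_compare <- length(control_ids) >= 2 && length(patient_ids) >= 2
  for (nm in names(idx_cols)) {
    fam <- lapply(c("ROC", "PDP", "RKG"), function(tk) {
      if (!can_compare)
        return(data.frame(index = nm, task = tk, U = NA, p = NA, A = NA,
                          n1 = length(control_ids), n2 = length(patient_ids),
                          computed = FALSE))
      ctrl <- pick(indices, idx_cols[[nm]], control_ids, tk)
      pat <- pick(indices, idx_cols[[nm]], patient_ids, tk)
      cmp <- mann_whitney(ctrl, pat)
      data.frame(index = nm, task = tk, U = cmp$statistic, p = cmp$p_value,
                 A = cmp$effect_A, n1 = cmp$n1, n2 = cmp$n2, computed = TRUE)
    })
    fam <- do.call(rbind, fam)
    fam$p_holm <- if (all(fam$computed)) holm_correct(fam$p) else NA_real_
    per_task <- rbind(per_task, fam)
  }

  # cross-task z summaries
  ztab <- z_summary(indices, control_ids)
  zcols <- c("z_dprime", "z_R", "z_F")
  z_comparisons <- NULL
  if (can_compare) {
    z_comparisons <- do.call(rbind, lapply(zcols, function(zc) {
      cmp <- mann_whitney(pick(ztab, zc, control_ids),
                          pick(ztab, zc, patient_ids))
      data.frame(index = zc, U = cmp$statistic, p = cmp$p_value,
                 A = cmp$effect_A, n1 = cmp$n1, n2 = cmp$n2)
    }))
    z_comparisons$p_holm <- holm_correct(z_comparisons$p)
  }

  # zR-zF correlation within each group
  correlations <- do.call(rbind, lapply(
    list(c("patient", "patient_ids"), c("control", "control_ids")),
    function(gg) {
      ids <- if (gg[1] == "patient") patient_ids else control_ids
      zr <- pick(ztab, "z_R", ids)
      zf <- pick(ztab, "z_F", ids)
      if (length(zr) < 3)
        return(data.frame(group = gg[1], rho = NA, p = NA, n = length(zr)))
      ct <- spearman_rho(zr, zf)
      data.frame(group = gg[1], rho = ct$rho, p = ct$p_value, n = ct$n)
    }))

  # subgroup permutation contrasts on the z summaries
  subgroup <- NULL
  if ("subgroup" %in% names(groups) && any(nzchar(groups$subgroup))) {
    dmtt <- groups$subject_id[groups$subgroup == "dMTT"]
    imtt <- groups$subject_id[groups$subgroup == "iMTT"]
    contrasts <- list(
      dMTT_vs_iMTT = list(dmtt, imtt),
      dMTT_vs_control = list(dmtt, control_ids),
      iMTT_vs_control = list(imtt, control_ids)
    )
    subgroup <- do.call(rbind, lapply(names(contrasts), function(cn) {
      g1 <- contrasts[[cn]][[1]]
      g2 <- contrasts[[cn]][[2]]
      do.call(rbind, lapply(zcols, function(zc) {
        a <- pick(ztab, zc, g1)
        b <- pick(ztab, zc, g2)
        if (length(a) < 2 || length(b) < 2)
          return(data.frame(contrast = cn, index = zc, stat = NA, p = NA,
                            A = NA, n1 = length(a), n2 = length(b),
                            computed = FALSE))
        cmp <- permutation_test(a, b, n_perm = n_perm, seed = seed)
        data.frame(contrast = cn, index = zc, stat = cmp$statistic,
                   p = cmp$p_value, A = cmp$effect_A,
                   n1 = cmp$n1, n2 = cmp$n2, computed = TRUE)
      }))
    }))
  }

  structure(
    list(per_task = per_task, z_comparisons = z_comparisons,
         z_table = ztab, correlations = correlations, subgroup = subgroup,
         excluded = attr(ztab, "excluded")),
    class = "recmem_results"
  )
}

#' @export
print.recmem_results <- function(x, ...) {
  cat("Recognition-memory group analysis\n\n")
  cat("Per-task patient-vs-control comparisons (Mann-Whitney):\n")
  print(format_num_df(x$per_task), row.names = FALSE)
  if (!is.null(x$z_comparisons)) {
    cat("\nCross-task z-summary comparisons:\n")
    print(format_num_df(x$z_comparisons), row.names = FALSE)
  }
  cat("\nzR-zF Spearman correlations:\n")
  print(format_num_df(x$correlations), row.names = FALSE)
  if (!is.null(x$subgroup)) {
    cat("\nSubgroup permutation contrasts:\n")
    print(format_num_df(x$subgroup), row.names = FALSE)
  }
  if (length(x$excluded))
    cat("\nExcluded from z summaries (missing task):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

format_num_df <- function(df, digits = 2) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}

#' Parameter-recovery experiment
#'
#' Simulates subjects with known latents, scores them with all three
#' estimators, and reports bias and RMSE of the recovered recollection and
#' familiarity indices, at the study's item counts (`scale = 1`) and at a
#' scaled-up design. Recollection estimates from every task are compared
#' with the generating `rho`. Familiarity comparators differ by scale: the
#' ROC `d_f` and the RKG z-difference estimate `delta` itself, while the
#' PDP familiarity is a probability and is compared with the generating
#' familiarity acceptance probability
#' \eqn{\Phi(\delta_{assoc} - c_{yes})}.
#'
#' @param config A [sim_config()]; subjects are drawn from its `group`
#'   distributions.
#' @param n_replicates Simulated subjects per scale.
#' @param seed RNG seed (global RNG is seeded once at entry).
#' @param scales Integer multipliers applied to every task's item counts.
#' @param group Group to draw subjects from (default `"control"`).
#' @return Data frame: `scale`, `estimator`, `index`, `bias`, `rmse`,
#'   `n_replicates`.
#' @export
recover_parameters <- function(config = sim_config(), n_replicates = 20L,
                               seed = 1L, scales = c(1L, 10L),
                               group = "control") {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  out <- NULL
  for (s in scales) {
    cfg <- config
    cfg$design <- lapply(config$design, function(d) d * s)
    err <- matrix(NA_real_, n_replicates, 6,
                  dimnames = list(NULL, c("roc_R", "roc_F", "pdp_R", "pdp_F",
                                          "rkg_R", "rkg_F")))
    for (r in seq_len(n_replicates)) {
      lat <- draw_subject(group, cfg)
      trials <- rbind(simulate_roc_trials(lat, cfg, "s", group),
                      simulate_pdp_trials(lat, cfg, "s", group),
                      simulate_rkg_trials(lat, cfg, "s", group))
      sc <- score_subjects(trials)
      f_pdp_true <- stats::pnorm(cfg$delta_assoc_frac * lat$delta -
                                   lat$yes_criterion)
      g <- function(tk, col) sc[[col]][sc$task == tk]
      err[r, ] <- c(g("ROC", "R_index") - lat$rho,
                    g("ROC", "F_index") - lat$delta,
                    g("PDP", "R_index") - lat$rho,
                    g("PDP", "F_index") - f_pdp_true,
                    g("RKG", "R_index") - lat$rho,
                    g("RKG", "F_index") - lat$delta)
    }
    est <- rep(c("roc", "pdp", "rkg"), each = 2)
    idx <- rep(c("R", "F"), 3)
    out <- rbind(out, data.frame(
      scale = s, estimator = est, index = idx,
      bias = colMeans(err), rmse = sqrt(colMeans(err^2)),
      n_replicates = n_replicates, row.names = NULL
    ))
  }
  out
}
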