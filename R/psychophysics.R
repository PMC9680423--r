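# Behavioural harness: 2AFC trials, psychometric functions, grid search
# and k-fold cross-validation.
#
# Within a trial block the stimulus (and hence the clean layer-3 activity)
# is identical; the only trial-to-trial variability is the internal output
# noise of the optic-flow-pattern neurons. The clean pipeline is therefore
# computed once per (angle, side) and cached on the model; each trial adds
# a fresh noise realization and integrates the decision network.

#' Train the full model
#'
#' Generates the training stimuli (both sides, the configured training
#' angle range, default 7-20 degrees), extracts opponent-motion features
#' and fits the 18 Gaussian stage templates.
#'
#' @param cfg a [bm_config()].
#' @return object of class `bm_model`: the config, the fitted
#'   `template_set`, the opponent geometry and an internal cache of clean
#'   per-stimulus traces.
#' @export
train_model <- function(cfg = bm_config()) {
  ocfg <- opponent_config(cfg)
  angles <- cfg$classifier$train_angles
  sides <- rep(c("right", "left"), each = length(angles))
  angs <- rep(angles, 2)
  feats <- mapply(function(a, s) {
    featurize(kick_sequence(s, a, cfg$stimulus$n_frames, cfg$stimulus$duration),
              cfg, ocfg)
  }, angs, sides, SIMPLIFY = FALSE)
  tpl <- fit_templates(feats, sides, cfg)
  structure(list(cfg = cfg, templates = tpl, ocfg = ocfg,
                 cache = new.env(parent = emptyenv())),
            class = "bm_model")
}

#' @export
print.bm_model <- function(x, ...) {
  cat(sprintf("biomotion model: %d-dim features, trained on angles %s (both sides)\n",
              x$templates$d, paste(range(x$cfg$classifier$train_angles), collapse = "-")))
  invisible(x)
}

# Clean (noise-free) pipeline state for one stimulus, cached on the model.
clean_trace <- function(model, angle, side) {
  key <- sprintf("%s_%.6f", side, angle)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  cfg <- model$cfg
  seq <- kick_sequence(side, angle, cfg$stimulus$n_frames, cfg$stimulus$duration)
  U <- featurize(seq, cfg, model$ocfg)
  G <- gate_series(U, model$templates)
  op <- ofp_params(cfg)
  H <- ofp_run(G, op)
  out <- list(U = U, G = G, H = H, ofp = op,
              E_right = colSums(H[1:9, , drop = FALSE]),
              E_left = colSums(H[10:18, , drop = FALSE]))
  model$cache[[key]] <- out
  out
}

# Decision for pre-drawn noisy layer-3 outputs (deterministic core shared
# by run_trial and run_block).
decide_from_noisy <- function(O, dt_in, dp, tie_seed = NULL) {
  res <- solve_decision(colSums(O[1:9, , drop = FALSE]),
                        colSums(O[10:18, , drop = FALSE]), dt_in, dp)
  w <- res$winner
  und <- w == "undecided"
  if (any(und)) {
    w[und] <- with_seed(tie_seed,
                        sample(c("right", "left"), sum(und), replace = TRUE))
  }
  list(winner = w, res = res)
}

#' Run a single 2AFC trial
#'
#' Full pipeline: stimulus -> features -> risk-Bayes gate -> optic-flow-
#' pattern dynamics with internal noise -> decision network -> left/right.
#'
#' @param model a trained `bm_model`.
#' @param angle deviation angle in degrees.
#' @param side true stimulus side, `"right"` or `"left"`.
#' @param seed seed for the trial's noise realization.
#' @return list with `decision`, `correct`, and the decision-network
#'   summary.
#' @export
run_trial <- function(model, angle, side, seed = NULL) {
  if (!inherits(model, "bm_model")) stop("run_trial needs a trained bm_model")
  ct <- clean_trace(model, angle, side)
  delta <- model$cfg$layer3$delta
  O <- with_seed(seed, add_internal_noise(ct$H, delta, ct$ofp$dt))
  dec <- decide_from_noisy(O, ct$ofp$dt, decision_params(model$cfg),
                           tie_seed = seed)
  list(decision = dec$winner[1], correct = dec$winner[1] == side,
       detail = dec$res)
}

#' Run a block of identical-stimulus trials
#'
#' @inheritParams run_trial
#' @param n_trials number of trials (default 120).
#' @return list with `decisions`, `n_correct`, `error_pct` and the block
#'   seed.
#' @export
run_block <- function(model, angle, side, n_trials = 120L, seed = NULL) {
  ct <- clean_trace(model, angle, side)
  delta <- model$cfg$layer3$delta
  dp <- decision_params(model$cfg)
  ns <- ncol(ct$H)
  draw <- function() {
    ER <- matrix(0, ns, n_trials); EL <- matrix(0, ns, n_trials)
    for (j in seq_len(n_trials)) {
      O <- add_internal_noise(ct$H, delta, ct$ofp$dt)
      ER[, j] <- colSums(O[1:9, , drop = FALSE])
      EL[, j] <- colSums(O[10:18, , drop = FALSE])
    }
    list(ER = ER, EL = EL)
  }
  E <- if (delta == 0) {
    list(ER = matrix(ct$E_right, ns, n_trials),
         EL = matrix(ct$E_left, ns, n_trials))
  } else with_seed(seed, draw())
  res <- solve_decision(E$ER, E$EL, ct$ofp$dt, dp)
  w <- res$winner
  und <- w == "undecided"
  if (any(und)) {
    w[und] <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                        sample(c("right", "left"), sum(und), replace = TRUE))
  }
  n_correct <- sum(w == side)
  list(decisions = w, n_correct = n_correct, n_trials = n_trials,
       error_pct = 100 * (1 - n_correct / n_trials), seed = seed)
}

#' Maximum-likelihood 2AFC psychometric fit
#'
#' Fits `p(correct | angle) = 0.5 + 0.5 * plogis(slope * (angle -
#' threshold))` by maximizing the binomial likelihood. The 75%-correct
#' point equals `threshold` by construction and `slope` is the logistic
#' rate parameter (per degree). Fits whose threshold falls below the
#' smallest (above the largest) tested angle are flagged floor- resp.
#' ceiling-limited rather than failing.
#'
#' @param angles tested angles (degrees).
#' @param n_correct correct counts per angle.
#' @param n_total trials per angle.
#' @return list `threshold`, `slope`, `loglik`, `converged`,
#'   `floor_limited`, `ceiling_limited`, and `fitted` proportions.
#' @export
fit_psychometric <- function(angles, n_correct, n_total) {
  stopifnot(length(angles) == length(n_correct),
            length(angles) == length(n_total), all(n_correct <= n_total))
  nll <- function(par) {
    p <- 0.5 + 0.5 * plogis(par[2] * (angles - par[1]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(n_correct * log(p) + (n_total - n_correct) * log(1 - p))
  }
  phat <- pmin(pmax(n_correct / n_total, 0.5 + 1e-6), 1 - 1e-6)
  # crude initial threshold: first angle whose observed p exceeds .75
  a0 <- angles[which(phat >= 0.75)[1]]
  if (is.na(a0)) a0 <- max(angles)
  fit <- optim(c(a0, 0.3), nll, method = "L-BFGS-B",
               lower = c(0.05, 1e-3), upper = c(100, 10))
  thr <- fit$par[1]; slp <- fit$par[2]
  list(threshold = thr, slope = slp, loglik = -fit$value,
       converged = fit$convergence == 0,
       floor_limited = thr < min(angles),
       ceiling_limited = thr > max(angles),
       fitted = 0.5 + 0.5 * plogis(slp * (angles - thr)))
}

#' Run the full 2AFC experiment and fit psychometric functions
#'
#' For each repetition: every angle is shown `n_trials` times per side,
#' the per-angle percent correct (sides pooled) is computed, and one
#' psychometric function is fitted. Threshold and slope are reported as
#' mean +/- SD over repetitions.
#'
#' @param model a trained `bm_model`.
#' @param angles tested angles (default from config: 2, 4, 8, 15).
#' @param n_trials trials per angle and side per repetition.
#' @param n_reps number of repetitions.
#' @param seed master seed; per-block seeds are derived from it.
#' @return object of class `bm_experiment`: per-repetition fits, the
#'   proportion-correct table, and `threshold_mean/sd`, `slope_mean/sd`.
#' @export
run_experiment <- function(model, angles = model$cfg$psychophysics$angles,
                           n_trials = model$cfg$psychophysics$n_trials,
                           n_reps = model$cfg$psychophysics$n_reps,
                           seed = 1L) {
  seeds <- matrix(derive_seeds(seed, n_reps * length(angles) * 2),
                  nrow = n_reps)
  fits <- vector("list", n_reps)
  prop <- matrix(NA_real_, n_reps, length(angles),
                 dimnames = list(NULL, paste0("deg", angles)))
  for (r in seq_len(n_reps)) {
    ncor <- integer(length(angles))
    s <- 0L
    for (a in seq_along(angles)) {
      for (side in c("right", "left")) {
        s <- s + 1L
        blk <- run_block(model, angles[a], side, n_trials,
                         seed = seeds[r, s])
        ncor[a] <- ncor[a] + blk$n_correct
      }
    }
    prop[r, ] <- ncor / (2 * n_trials)
    fits[[r]] <- fit_psychometric(angles, ncor, rep(2L * n_trials, length(angles)))
  }
  thr <- vapply(fits, `[[`, 0, "threshold")
  slp <- vapply(fits, `[[`, 0, "slope")
  structure(list(
    fits = fits, prop_correct = prop, angles = angles,
    n_trials = n_trials, n_reps = n_reps, seed = seed,
    threshold_mean = mean(thr), threshold_sd = sd(thr),
    slope_mean = mean(slp), slope_sd = sd(slp),
    floor_limited = vapply(fits, `[[`, TRUE, "floor_limited")
  ), class = "bm_experiment")
}

#' @export
print.bm_experiment <- function(x, ...) {
  cat(sprintf("2AFC experiment: %d reps x %d trials/angle/side, angles %s\n",
              x$n_reps, x$n_trials, paste(x$angles, collapse = ", ")))
  cat(sprintf("  75%% threshold: %.3f +/- %.3f deg\n",
              x$threshold_mean, x$threshold_sd))
  cat(sprintf("  slope:         %.4f +/- %.4f per deg\n",
              x$slope_mean, x$slope_sd))
  if (any(x$floor_limited))
    cat(sprintf("  note: %d/%d repetitions floor-limited\n",
                sum(x$floor_limited), x$n_reps))
  invisible(x)
}

#' Grid search over internal noise, time constant and inhibitory gain
#'
#' Runs [run_experiment()] for every cell of the `delta x tau x k` grid.
#' The templates do not depend on these parameters, so the model is
#' trained once and shared. Per-cell seeds are derived deterministically
#' from the master seed and the cell coordinates; cell failures are
#' isolated and reported in the `error` column.
#'
#' @param cfg a [bm_config()].
#' @param delta,tau,k parameter vectors spanning the grid.
#' @param angles,n_trials,n_reps experiment scale.
#' @param seed master seed.
#' @param model optionally a pre-trained model (to share across calls).
#' @return data.frame, one row per cell: parameters, threshold/slope
#'   mean and SD, floor-limited count, error message (or NA).
#' @export
grid_search <- function(cfg = bm_config(), delta, tau, k,
                        angles = cfg$psychophysics$angles,
                        n_trials = cfg$psychophysics$n_trials,
                        n_reps = cfg$psychophysics$n_reps,
                        seed = 1L, model = NULL) {
  if (is.null(model)) model <- train_model(cfg)
  cells <- expand.grid(delta = delta, tau = tau, k = k,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    m <- model
    m$cfg$layer3$delta <- ci$delta
    m$cfg$layer4$tau <- ci$tau
    m$cfg$layer4$k <- ci$k
    rows[[i]] <- tryCatch({
      ex <- run_experiment(m, angles, n_trials, n_reps, seed = cell_seeds[i])
      data.frame(ci, threshold_mean = ex$threshold_mean,
                 threshold_sd = ex$threshold_sd,
                 slope_mean = ex$slope_mean, slope_sd = ex$slope_sd,
                 n_floor_limited = sum(ex$floor_limited),
                 seed = cell_seeds[i], error = NA_character_)
    }, error = function(e) {
      data.frame(ci, threshold_mean = NA_real_, threshold_sd = NA_real_,
                 slope_mean = NA_real_, slope_sd = NA_real_,
                 n_floor_limited = NA_integer_, seed = cell_seeds[i],
                 error = conditionMessage(e))
    })
  }
  do.call(rbind, rows)
}

#' Stratified k-fold cross-validation of the stage classifier
#'
#' Builds the stimulus set over `angles` (both sides), assigns sequences
#' to folds stratified by side (angles dealt round-robin after a seeded
#' shuffle), and for each fold fits templates on the training folds and
#' evaluates held-out sequences. Two evaluation units are supported:
#' `"vector"` classifies every held-out frame-pair feature vector with the
#' risk classifier (reporting both 18-class and side accuracy), and
#' `"sequence"` runs the full noise-free pipeline on each held-out
#' sequence and scores the final left/right decision.
#'
#' @param cfg a [bm_config()].
#' @param folds number of folds (default 5).
#' @param angles training/validation angle range (default 1-20 degrees).
#' @param unit `"vector"` or `"sequence"` (default from config).
#' @param seed seed for the fold shuffle.
#' @return list: `accuracy` (side-level), `accuracy_class` (18-class,
#'   vector unit only), `per_fold`, `n`, `unit`.
#' @export
cross_validate <- function(cfg = bm_config(), folds = 5L, angles = 1:20,
                           unit = cfg$psychophysics$cv_unit, seed = 1L) {
  unit <- match.arg(unit, c("vector", "sequence"))
  ocfg <- opponent_config(cfg)
  grid <- expand.grid(angle = angles, side = c("right", "left"),
                      stringsAsFactors = FALSE)
  feats <- mapply(function(a, s) {
    featurize(kick_sequence(s, a, cfg$stimulus$n_frames, cfg$stimulus$duration),
              cfg, ocfg)
  }, grid$angle, grid$side, SIMPLIFY = FALSE)

  # stratified fold assignment: within each side, shuffle angles then deal
  fold <- integer(nrow(grid))
  sh <- derive_seeds(seed, 2)
  for (i in 1:2) {
    sel <- which(grid$side == c("right", "left")[i])
    ord <- with_seed(sh[i], sample(sel))
    fold[ord] <- rep_len(seq_len(folds), length(ord))
  }

  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!all(c("right", "left") %in% grid$side[tr]))
      stop("fold with an empty class: too many folds for the stimulus set")
    tpl <- fit_templates(feats[tr], grid$side[tr], cfg)
    if (unit == "vector") {
      hit_side <- 0L; hit_class <- 0L; n <- 0L
      for (j in te) {
        res <- classify_risk(feats[[j]], tpl)
        stages <- stage_of_pair(seq_len(nrow(feats[[j]])), cfg$classifier$stage_len)
        truth <- class_index(stages, grid$side[j])
        hit_class <- hit_class + sum(res$winner == truth)
        hit_side <- hit_side + sum(res$side == grid$side[j])
        n <- n + nrow(feats[[j]])
      }
      per_fold[[f]] <- c(n = n, hit_side = hit_side, hit_class = hit_class)
    } else {
      op <- ofp_params(cfg)
      dp <- decision_params(cfg)
      hit <- 0L
      for (j in te) {
        G <- gate_series(feats[[j]], tpl)
        H <- ofp_run(G, op)
        dec <- decide_from_noisy(H, op$dt, dp, tie_seed = seed + j)
        hit <- hit + (dec$winner[1] == grid$side[j])
      }
      per_fold[[f]] <- c(n = length(te), hit_side = hit, hit_class = NA)
    }
  }
  tot <- Reduce(`+`, lapply(per_fold, function(x) x[c("n", "hit_side")]))
  acc_class <- if (unit == "vector")
    sum(vapply(per_fold, `[[`, 0, "hit_class")) / tot[["n"]] else NA_real_
  list(accuracy = tot[["hit_side"]] / tot[["n"]],
       accuracy_class = acc_class,
       per_fold = per_fold, n = tot[["n"]], unit = unit, folds = folds)
}
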