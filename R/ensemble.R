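#' Stratified random cross-validation splits
#'
#' Random 80/20 train/test splits, repeated \code{runs} times, stratified by
#' role so presences and background records both appear in every train and
#' test fold. Deterministic for a fixed seed.
#'
#' @param occ An \code{occurrence_set} or any data.frame with a \code{role}
#'   column (or a model table with \code{pa}).
#' @param runs Number of repeats (default 5).
#' @param train_fraction Fraction in the training fold (default 0.8).
#' @param seed Integer seed.
#' @return List of length \code{runs}; each element a list with integer index
#'   vectors \code{train} and \code{test} (disjoint, covering all rows).
#' @export
cv_split <- function(occ, runs = 5, train_fraction = 0.8, seed = 1) {
  pa <- if ("pa" %in% colnames(occ)) occ$pa == 1 else occ$role == "presence"
  n_pres <- sum(pa); n_bg <- sum(!pa)
  if (n_pres < 10 || n_bg < 10)
    stop("need at least 10 presences and 10 background records to stratify",
         call. = FALSE)
  idx_p <- which(pa); idx_b <- which(!pa)
  withr::with_seed(seed, lapply(seq_len(runs), function(r) {
    tr_p <- sample(idx_p, round(train_fraction * n_pres))
    tr_b <- sample(idx_b, round(train_fraction * n_bg))
    train <- sort(c(tr_p, tr_b))
    list(train = train, test = setdiff(seq_along(pa), train))
  }))
}

#' Evaluate suitability scores against presence/background labels
#'
#' The binarization threshold is chosen to maximise the True Skill Statistic
#' over all candidate thresholds (midpoints of sorted distinct scores);
#' sensitivity and specificity are reported at that threshold, and
#' \code{TSS = sensitivity + specificity - 1} holds exactly. AUC uses the
#' rank (Mann-Whitney) formulation with ties averaged. Background records are
#' treated as absences.
#'
#' @param scores Numeric suitability scores.
#' @param labels Binary labels (1/TRUE = presence).
#' @return List with \code{tss}, \code{auc}, \code{sensitivity},
#'   \code{specificity}, \code{threshold}.
#' @export
evaluate_scores <- function(scores, labels) {
  y <- as.logical(labels)
  if (all(y) || !any(y)) stop("both classes must be present", call. = FALSE)
  n1 <- sum(y); n0 <- sum(!y)

  # candidate thresholds: midpoints of sorted unique scores (plus outer
  # guards so all-positive / all-negative classifications are reachable)
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  cand <- c(min(u) - 1e-9, cand, max(u) + 1e-9)

  # vectorised confusion at each threshold: predict presence when score >= t
  s_sorted <- sort(scores)
  y_by_score <- y[order(scores)]
  cum_pos <- cumsum(y_by_score)           # positives with score <= s_sorted[k]
  pos_below <- findInterval(cand, s_sorted, left.open = TRUE)  # scores < t
  cum_pos0 <- c(0, cum_pos)                    # guard for pos_below == 0
  tp <- n1 - cum_pos0[pos_below + 1]
  fp <- (n0 + n1 - pos_below) - tp
  sens <- tp / n1
  spec <- (n0 - fp) / n0
  tss <- sens + spec - 1
  best <- which.max(tss)

  list(tss = tss[best], auc = auc_rank(scores, y),
       sensitivity = sens[best], specificity = spec[best],
       threshold = cand[best])
}

#' AUC via the rank (Mann-Whitney) formulation
#'
#' Probability that a random presence outscores a random background point,
#' ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired t-test on per-run metric scores
#'
#' Compares two models' cross-validation scores run by run with the classic
#' paired t statistic. Zero-variance differences are degenerate rather than an
#' error: identical vectors give t = 0; a constant non-zero difference gives
#' t = +/-Inf, with \code{degenerate = TRUE} in both cases.
#'
#' @param evals_a,evals_b Numeric vectors of per-run scores, equal length >= 2.
#' @return List with \code{t}, \code{df}, \code{p_value}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
paired_metric_test <- function(evals_a, evals_b) {
  stopifnot(length(evals_a) == length(evals_b), length(evals_a) >= 2)
  d <- evals_a - evals_b
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = length(d) - 1, p_value = if (md == 0) 1 else 0,
                mean_diff = md, degenerate = TRUE))
  }
  tt <- stats::t.test(evals_a, evals_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Fit and cross-validate all registry members
#'
#' Each (model, run) pair is fitted on the run's training fold and evaluated
#' on the held-out fold; after evaluation every member is refitted on the full
#' table for projection. A member that errors is flagged and excluded rather
#' than aborting the run.
#'
#' @param table Model table from \code{\link{build_model_table}}.
#' @param specs Named list of \code{model_spec}s.
#' @param splits Output of \code{\link{cv_split}} on the same table.
#' @param variables Predictor column names.
#' @return List with \code{evals} (data.frame: model, run, tss, auc,
#'   sensitivity, specificity, threshold), \code{members} (full-data refits),
#'   and \code{failed} (labels of members that errored).
#' @export
fit_members <- function(table, specs, splits,
                        variables = c("SST", "CHL", "SSS", "MLD", "CV")) {
  evals <- list()
  failed <- character(0)
  for (nm in names(specs)) {
    res <- tryCatch({
      rows <- lapply(seq_along(splits), function(r) {
        sp <- splits[[r]]
        member <- fit_model(specs[[nm]], table[sp$train, , drop = FALSE],
                            variables)
        sc <- predict_model(member, table[sp$test, , drop = FALSE])
        ev <- evaluate_scores(sc, table$pa[sp$test])
        data.frame(model = nm, run = r, tss = ev$tss, auc = ev$auc,
                   sensitivity = ev$sensitivity,
                   specificity = ev$specificity, threshold = ev$threshold)
      })
      do.call(rbind, rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("member '%s' failed and is excluded: %s",
                      nm, conditionMessage(res)), call. = FALSE)
      failed <- c(failed, nm)
    } else {
      evals[[nm]] <- res
    }
  }
  ok <- setdiff(names(specs), failed)
  members <- lapply(ok, function(nm) fit_model(specs[[nm]], table, variables))
  names(members) <- ok
  list(evals = do.call(rbind, c(evals, list(make.row.names = FALSE))),
       members = members, failed = failed)
}

#' Select ensemble members and their weights
#'
#' Members with mean-across-runs TSS at or above the selection threshold enter
#' the ensemble; weighted-mean weights are proportional to (mean TSS)^exponent
#' and normalised to sum to one. Per-member binarization thresholds (used by
#' committee averaging) are the mean of the per-run max-TSS thresholds.
#'
#' @param evals Evaluation table from \code{\link{fit_members}}.
#' @param tss_min Selection threshold on mean TSS (default 0.8).
#' @param weight_exponent Exponent on mean TSS in the weights (default 1).
#' @return List with \code{selected}, \code{weights}, \code{mean_tss},
#'   \code{thresholds}.
#' @export
select_members <- function(evals, tss_min = 0.8, weight_exponent = 1) {
  mean_tss <- tapply(evals$tss, evals$model, mean)
  thresholds <- tapply(evals$threshold, evals$model, mean)
  selected <- names(mean_tss)[mean_tss >= tss_min]
  if (length(selected) == 0)
    stop(sprintf(
      "no member passes the selection rule mean CV TSS >= %.2f (best: %.3f)",
      tss_min, max(mean_tss)), call. = FALSE)
  w <- mean_tss[selected]^weight_exponent
  list(selected = selected, weights = w / sum(w),
       mean_tss = mean_tss, thresholds = thresholds)
}

#' Assemble a fitted ensemble
#'
#' @param fits Output of \code{\link{fit_members}}.
#' @param selection Output of \code{\link{select_members}}.
#' @param combiner One of \code{"EMwmean"} (TSS-weighted mean, the default
#'   reporting model), \code{"EMmean"}, \code{"EMmedian"}, \code{"EMca"}
#'   (committee averaging of binary member maps).
#' @return Object of class \code{sdm_ensemble}.
#' @export
sdm_ensemble <- function(fits, selection, combiner = "EMwmean") {
  stopifnot(combiner %in% c("EMmean", "EMmedian", "EMca", "EMwmean"))
  members <- fits$members[selection$selected]
  structure(list(members = members, weights = selection$weights,
                 thresholds = selection$thresholds[selection$selected],
                 mean_tss = selection$mean_tss[selection$selected],
                 combiner = combiner,
                 variables = members[[1]]$variables),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble %s> %d member(s): %s\n", x$combiner,
              length(x$members),
              paste(sprintf("%s (TSS %.3f, w %.3f)", names(x$members),
                            x$mean_tss, x$weights), collapse = ", ")))
  invisible(x)
}

#' Combine member scores under an ensemble rule
#'
#' \code{EMmean}: cellwise mean. \code{EMmedian}: cellwise median.
#' \code{EMwmean}: cellwise weighted mean with weights proportional to mean
#' CV TSS. \code{EMca}: committee averaging — cellwise mean of the members'
#' binary predictions, each binarized at its own max-TSS threshold.
#'
#' @param score_matrix Numeric matrix, one column per member (rows = cells or
#'   records).
#' @param rule Combiner name.
#' @param weights Member weights (EMwmean; must sum to 1).
#' @param thresholds Per-member binarization thresholds (EMca).
#' @return Numeric vector of combined scores in [0, 1].
#' @export
combine_scores <- function(score_matrix, rule, weights = NULL,
                           thresholds = NULL) {
  score_matrix <- as.matrix(score_matrix)
  switch(rule,
    EMmean = rowMeans(score_matrix),
    EMmedian = apply(score_matrix, 1, stats::median),
    EMwmean = {
      stopifnot(!is.null(weights), length(weights) == ncol(score_matrix))
      as.numeric(score_matrix %*% (weights / sum(weights)))
    },
    EMca = {
      stopifnot(!is.null(thresholds),
                length(thresholds) == ncol(score_matrix))
      bin <- sweep(score_matrix, 2, thresholds, ">=")
      rowMeans(bin)
    },
    stop(sprintf("unknown combiner '%s'", rule), call. = FALSE))
}

#' Predict ensemble suitability on a table
#'
#' @param ensemble An \code{sdm_ensemble}.
#' @param table data.frame with the ensemble's predictor columns.
#' @param rule Combiner override (defaults to the ensemble's own).
#' @return Suitability scores in [0, 1].
#' @export
predict_ensemble <- function(ensemble, table, rule = ensemble$combiner) {
  sm <- vapply(ensemble$members, predict_model, numeric(nrow(table)),
               table = table)
  sm <- matrix(sm, nrow = nrow(table))
  combine_scores(sm, rule, weights = ensemble$weights,
                 thresholds = ensemble$thresholds)
}

#' Combine member suitability maps
#'
#' @param member_maps List of \code{hsi_map}s on a shared grid, one per
#'   selected member (order matching \code{weights}/\code{thresholds}).
#' @inheritParams combine_scores
#' @return An \code{hsi_map}.
#' @export
combine_maps <- function(member_maps, rule, weights = NULL,
                         thresholds = NULL) {
  g <- member_maps[[1]]$grid
  for (m in member_maps)
    if (!identical(dim(m$hsi), c(g$ny, g$nx)))
      stop("member maps on different grids", call. = FALSE)
  sm <- vapply(member_maps, function(m) as.vector(m$hsi),
               numeric(g$ny * g$nx))
  comb <- combine_scores(matrix(sm, ncol = length(member_maps)), rule,
                         weights = weights, thresholds = thresholds)
  hsi_map(g, matrix(comb, g$ny, g$nx),
          tag = paste0(rule, ":", member_maps[[1]]$tag))
}

#' Permutation variable importance
#'
#' For each predictor: permute its column, re-predict, and measure
#' \code{1 - cor(original predictions, permuted predictions)}, averaged over
#' permutations; contributions are rescaled to sum to 100. A variable the
#' model ignores scores ~0. Constant predictions make the correlation
#' undefined; such variables are reported as 0 with a warning.
#'
#' @param object An \code{sdm_ensemble} or \code{sdm_member}.
#' @param table Model table (typically the fitting table).
#' @param seed Integer seed for the permutations.
#' @param permutations Number of permutations per variable (default 3).
#' @return data.frame with \code{variable}, \code{importance} (raw mean
#'   1 - r), \code{contribution_pct}.
#' @export
variable_importance <- function(object, table, seed = 1, permutations = 3) {
  variables <- if (inherits(object, "sdm_ensemble")) object$variables
               else object$variables
  stopifnot(length(variables) >= 2)
  pred_fun <- if (inherits(object, "sdm_ensemble")) predict_ensemble
              else predict_model
  base <- pred_fun(object, table)
  raw <- withr::with_seed(seed, vapply(variables, function(v) {
    mean(vapply(seq_len(permutations), function(p) {
      tab <- table
      tab[[v]] <- sample(tab[[v]])
      prm <- pred_fun(object, tab)
      if (stats::sd(base) == 0 || stats::sd(prm) == 0) {
        warning(sprintf("constant predictions while permuting '%s'; importance 0",
                        v), call. = FALSE)
        return(0)
      }
      1 - stats::cor(base, prm)
    }, numeric(1)))
  }, numeric(1)))
  contrib <- if (sum(raw) > 0) 100 * raw / sum(raw) else raw * 0
  data.frame(variable = variables, importance = unname(raw),
             contribution_pct = unname(contrib), row.names = NULL)
}

#' Response curve by the evaluation-strip method
#'
#' Sweeps one predictor over its observed range at \code{n_points} evenly
#' spaced values while holding every other predictor at its median, and
#' evaluates the model along the strip. By default the medians are taken over
#' presence rows when the table carries a \code{pa} column: the strip then
#' represents typical occupied conditions, so the swept variable's effect is
#' read at an ecologically meaningful operating point instead of deep in
#' background (pseudo-absence) conditions, where presence-background tables
#' would otherwise pin every other variable far off-niche.
#'
#' @param object An \code{sdm_ensemble} or \code{sdm_member}.
#' @param table Model table supplying the observed ranges and medians.
#' @param variable Predictor to sweep.
#' @param n_points Number of evaluation points (1 gives the range midpoint).
#' @param at \code{"presence"} (default; falls back to all rows when no
#'   \code{pa} column) or \code{"all"}: which rows supply the medians.
#' @return data.frame with \code{value} and \code{suitability}.
#' @export
response_curve <- function(object, table, variable, n_points = 100,
                           at = c("presence", "all")) {
  at <- match.arg(at)
  variables <- object$variables
  stopifnot(variable %in% variables)
  rng <- range(table[[variable]], na.rm = TRUE)
  xs <- if (n_points == 1) mean(rng)
        else seq(rng[1], rng[2], length.out = n_points)
  ref <- if (at == "presence" && "pa" %in% colnames(table))
    table[table$pa == 1, , drop = FALSE] else table
  strip <- as.data.frame(lapply(ref[, variables, drop = FALSE],
                                function(col) rep(stats::median(col),
                                                  length(xs))))
  strip[[variable]] <- xs
  pred_fun <- if (inherits(object, "sdm_ensemble")) predict_ensemble
              else predict_model
  data.frame(value = xs, suitability = pred_fun(object, strip))
}

#' Cross-validated skill of an ensemble rule
#'
#' Rebuilds the combined prediction on each run's held-out fold from the
#' per-run member fits (members selected and weighted by their mean CV TSS)
#' and evaluates it, giving the ensemble the same held-out treatment as its
#' members.
#'
#' @param table Model table.
#' @param specs Registry used in \code{\link{fit_members}}.
#' @param splits The same CV splits.
#' @param evals Evaluation table from \code{\link{fit_members}}.
#' @param rule Combiner.
#' @param tss_min Member-selection threshold.
#' @return data.frame with one row per run: \code{run}, \code{tss},
#'   \code{auc}, \code{sensitivity}, \code{specificity}, \code{threshold}.
#' @export
ensemble_cv_skill <- function(table, specs, splits, evals, rule = "EMwmean",
                              tss_min = 0.8) {
  sel <- select_members(evals, tss_min = tss_min)
  variables <- intersect(colnames(table),
                         c("SST", "CHL", "SSS", "MLD", "CV", "Uo", "Vo"))
  rows <- lapply(seq_along(splits), function(r) {
    sp <- splits[[r]]
    sm <- vapply(sel$selected, function(nm) {
      member <- fit_model(specs[[nm]], table[sp$train, , drop = FALSE],
                          variables)
      predict_model(member, table[sp$test, , drop = FALSE])
    }, numeric(length(sp$test)))
    comb <- combine_scores(matrix(sm, ncol = length(sel$selected)), rule,
                           weights = sel$weights,
                           thresholds = sel$thresholds[sel$selected])
    ev <- evaluate_scores(comb, table$pa[sp$test])
    data.frame(run = r, tss = ev$tss, auc = ev$auc,
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               threshold = ev$threshold)
  })
  do.call(rbind, rows)
}
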