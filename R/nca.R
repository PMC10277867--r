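#' @title Non-compartmental analysis and two-fold qualification
#' @name pk_metrics
NULL

#' Non-compartmental analysis of a concentration-time profile
#'
#' AUC(0-t) by the linear trapezoid on the given grid; Cmax/Tmax from the
#' grid maximum; the terminal slope (lambda_z) from a log-linear fit of
#' the terminal phase. The terminal-point rule is fixed: among suffixes
#' (>= 3 points) of the observations after Tmax with concentration below
#' Cmax/2, take the one maximizing adjusted r-squared and require
#' adjusted r-squared >= 0.9, else lambda_z is left undefined and flagged.
#' AUC(0-inf) adds `Clast / lambda_z`.
#'
#' @param time increasing time grid, h (>= 3 points)
#' @param conc concentrations, ng/mL
#' @return object of class `pk_summary`: `auc_0_t`, `auc_0_inf`, `cmax`,
#'   `tmax`, `lambda_z`, `extrapolated_fraction`, `lambda_z_flag`
#' @export
nca <- function(time, conc) {
  stopifnot(length(time) == length(conc), length(time) >= 3)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(conc < 0)) stop("negative concentrations")
  auc_t <- sum(diff(time) * (head(conc, -1) + conc[-1]) / 2)
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- time[imax]
  if (cmax == 0) {
    return(structure(list(auc_0_t = 0, auc_0_inf = 0, cmax = 0,
                          tmax = tmax, lambda_z = NA_real_,
                          extrapolated_fraction = 0,
                          lambda_z_flag = "all-zero profile"),
                     class = "pk_summary"))
  }
  cand <- which(seq_along(conc) > imax & conc < cmax / 2 & conc > 0)
  lambda <- NA_real_; flag <- NA_character_
  if (length(cand) >= 3) {
    # closed-form log-linear regression per candidate suffix; on dense
    # simulated grids the candidate starts are thinned to at most 25
    n_start <- length(cand) - 2
    starts <- if (n_start > 25) {
      unique(round(seq(1, n_start, length.out = 25)))
    } else seq_len(n_start)
    best_r2 <- -Inf
    for (start in starts) {
      idx <- cand[start:length(cand)]
      x <- time[idx]; yv <- log(conc[idx]); n <- length(idx)
      sxx <- sum((x - mean(x))^2)
      sxy <- sum((x - mean(x)) * (yv - mean(yv)))
      syy <- sum((yv - mean(yv))^2)
      if (sxx == 0 || syy == 0) next
      slope <- sxy / sxx
      r2 <- (sxy^2 / (sxx * syy))
      adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
      if (is.finite(adj_r2) && adj_r2 > best_r2 && slope < 0) {
        best_r2 <- adj_r2; lambda <- -slope
      }
    }
    if (!is.finite(best_r2) || best_r2 < 0.9) {
      lambda <- NA_real_
      flag <- "terminal fit adj r2 < 0.9"
    }
  } else {
    flag <- "fewer than 3 terminal points"
  }
  if (!is.na(lambda)) {
    extrap <- conc[length(conc)] / lambda
    auc_inf <- auc_t + extrap
    ef <- extrap / auc_inf
  } else {
    auc_inf <- NA_real_; ef <- NA_real_
  }
  structure(list(auc_0_t = auc_t, auc_0_inf = auc_inf, cmax = cmax,
                 tmax = tmax, lambda_z = lambda,
                 extrapolated_fraction = ef, lambda_z_flag = flag),
            class = "pk_summary")
}

#' @export
print.pk_summary <- function(x, ...) {
  cat(sprintf("<pk_summary> AUC0-t %.4g, AUC0-inf %.4g ng.h/mL; Cmax %.4g ng/mL at %.3g h\n",
              x$auc_0_t, x$auc_0_inf, x$cmax, x$tmax))
  if (!is.na(x$lambda_z))
    cat(sprintf("  lambda_z %.4g 1/h (extrapolated %.1f%%)\n", x$lambda_z,
                100 * x$extrapolated_fraction))
  invisible(x)
}

#' NCA of a simulation result
#' @param result a `sim_result`
#' @return a `pk_summary` of the venous plasma profile
#' @export
nca_sim <- function(result) {
  nca(result$time, result$plasma_concentration)
}

#' Fold error between an observed and a predicted value
#'
#' `max(observed/predicted, predicted/observed)`: always >= 1, symmetric
#' in its arguments, and scale invariant. A fold error of at most 2 is
#' the conventional PBPK qualification bound.
#'
#' @param observed,predicted positive values (vectorized)
#' @return fold error >= 1
#' @export
fold_error <- function(observed, predicted) {
  if (any(observed <= 0) || any(predicted <= 0)) {
    stop("fold_error requires positive inputs")
  }
  pmax(observed / predicted, predicted / observed)
}

#' Two-fold qualification of predictions against observed PK parameters
#'
#' @param predicted data.frame with columns `dose_mg`, `auc`, `cmax`,
#'   `tmax` (predicted values per dose)
#' @param observed data.frame with the same columns (observed values);
#'   doses must match one-to-one
#' @param threshold qualification bound on the fold error (default 2)
#' @return object of class `fold_error_report`: long data.frame `table`
#'   (dose, parameter, predicted, observed, fold_error, pass) and scalar
#'   `overall_pass`
#' @export
qualify <- function(predicted, observed, threshold = 2) {
  need <- c("dose_mg", "auc", "cmax", "tmax")
  stopifnot(all(need %in% names(predicted)), all(need %in% names(observed)))
  unmatched <- setdiff(observed$dose_mg, predicted$dose_mg)
  if (length(unmatched)) {
    stop("no prediction for observed dose(s): ",
         paste(unmatched, collapse = ", "))
  }
  rows <- list()
  for (k in seq_len(nrow(observed))) {
    d <- observed$dose_mg[k]
    p <- predicted[match(d, predicted$dose_mg), ]
    for (par in c("auc", "cmax", "tmax")) {
      fe <- fold_error(observed[[par]][k], p[[par]])
      rows[[length(rows) + 1L]] <- data.frame(
        dose_mg = d, parameter = par, predicted = p[[par]],
        observed = observed[[par]][k], fold_error = fe,
        pass = fe <= threshold)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 overall_pass = all(tab$pass[tab$parameter != "tmax"]),
                 overall_pass_incl_tmax = all(tab$pass),
                 threshold = threshold),
            class = "fold_error_report")
}

#' @export
print.fold_error_report <- function(x, ...) {
  cat(sprintf("<fold_error_report> threshold %.3g; AUC/Cmax pass: %s; incl. Tmax: %s\n",
              x$threshold, x$overall_pass, x$overall_pass_incl_tmax))
  print(x$table, row.names = FALSE)
  invisible(x)
}
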