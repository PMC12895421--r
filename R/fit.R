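#' Fit plan: staging, fixed coefficients, optimizer settings
#'
#' A fit proceeds order by order: each stage raises the per-interaction
#' caps (up to the final caps), warm-starts from the previous optimum,
#' activates the newly allowed coefficients at zero and refits all active
#' coefficients by Levenberg--Marquardt least squares.
#'
#' @param caps final per-interaction caps (single order or named
#'   \code{c(elec =, ind =, disp =)}).
#' @param stages optional list of caps vectors, strictly increasing in at
#'   least one cap; by default one stage per overall order from the lowest
#'   allowed term to \code{max(caps)}.
#' @param fixed named numeric vector of coefficients held fixed (layout
#'   names such as \code{"QA.1.1"}, or Stone-label forms like
#'   \code{"QB.20"} where unambiguous).
#' @param far_fraction fraction of largest-R points used by the
#'   initialization prefit (default 0.25).
#' @param ftol,ptol,maxit Levenberg--Marquardt tolerances and iteration cap
#'   per stage.
#' @param seed integer seed (stochastic components of a fit, if any, and
#'   bookkeeping for reproducibility).
#' @return an object of class \code{lr_plan}.
#' @export
lr_plan <- function(caps = 6, stages = NULL, fixed = NULL,
                    far_fraction = 0.25, ftol = 1e-12, ptol = 1e-10,
                    maxit = 2000L, seed = 1L) {
  caps <- .norm_caps(caps)
  if (!is.null(stages)) {
    stages <- lapply(stages, .norm_caps)
    for (i in seq_along(stages)[-1L]) {
      if (!any(stages[[i]] > stages[[i - 1L]]))
        stop("stages must be strictly increasing in at least one cap")
    }
  }
  structure(list(caps = caps, stages = stages, fixed = fixed,
                 far_fraction = far_fraction, ftol = ftol, ptol = ptol,
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "lr_plan")
}

## default staging: one stage per overall order, dropping stages that do
## not change the active term set
.default_stages <- function(expansion, caps) {
  tab <- expansion$terms
  if (nrow(tab) == 0L) return(list(caps))
  n0 <- min(tab$order)
  stages <- list(); prev_n <- -1L
  for (n in n0:max(caps)) {
    cn <- pmin(caps, n)
    nt <- sum((tab$interaction == "electrostatic" & tab$order <= cn[["elec"]]) |
              (grepl("^induction", tab$interaction) & tab$order <= cn[["ind"]]) |
              (tab$interaction == "dispersion" & tab$order <= cn[["disp"]]))
    if (nt > prev_n) {
      stages[[length(stages) + 1L]] <- cn
      prev_n <- nt
    }
  }
  stages
}

#' Fit statistics
#'
#' @param residuals numeric residual vector (model minus data).
#' @param observed the fitted data values.
#' @return named vector \code{c(rmse, r2)}; \code{r2} is \code{NA} for
#'   zero-variance data.
#' @export
fit_statistics <- function(residuals, observed) {
  stopifnot(length(residuals) == length(observed), length(observed) >= 2L)
  rmse <- sqrt(mean(residuals^2))
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sum(residuals^2) / sst else NA_real_
  c(rmse = rmse, r2 = r2)
}

## order-activation map: for every full parameter, the smallest cap of
## each interaction at which some term using it is active
.par_activation <- function(expansion) {
  nms <- expansion$names
  act <- matrix(Inf, length(nms), 3L,
                dimnames = list(nms, c("elec", "ind", "disp")))
  act["E_asym", ] <- 0
  tab <- expansion$terms
  for (i in seq_len(nrow(tab))) {
    p <- strsplit(tab$key[i], ".", fixed = TRUE)[[1]]
    n <- tab$order[i]
    touch <- function(pat, col) {
      j <- grep(pat, nms)
      act[j, col] <<- pmin(act[j, col], n)
    }
    switch(substr(p[1], 1, 1),
      E = {
        touch(sprintf("^QA\\.%s\\.", p[2]), "elec")
        touch(sprintf("^QB\\.%s\\.", p[3]), "elec")
      },
      I = {
        side <- substr(p[1], 2, 2); oth <- if (side == "A") "B" else "A"
        touch(sprintf("^a%s\\.%s\\.", side, p[2]), "ind")
        touch(sprintf("^Q%s\\.%s\\.", oth, p[3]), "ind")
        touch(sprintf("^Q%s\\.%s\\.", oth, p[4]), "ind")
      },
      D = touch(sprintf("^D\\.%s\\|%s\\.", p[2], p[3]), "disp"))
  }
  act
}

.active_free <- function(act, tie, caps) {
  full_on <- act[, "elec"] <= caps[["elec"]] | act[, "ind"] <= caps[["ind"]] |
    act[, "disp"] <= caps[["disp"]]
  on <- as.logical(t(tie$Tmat != 0) %*% full_on > 0)
  on[tie$free_names == "E_asym"] <- TRUE
  on
}

#' Initialize a fit from the far long range
#'
#' Linear least-squares prefit on the largest-R portion of the data using
#' only the terms of the first two leading orders, estimating the
#' asymptotic energy together with the lumped coefficient products of
#' those terms; per-molecule values are then back-assigned by a cascade
#' (anchored at pinned charges where available, otherwise by a rank-one
#' factorization with the sign gauge applied).  All other coefficients
#' start at zero.
#'
#' @param data an [lr_dataset()].
#' @param sys an [lr_system()].
#' @param plan an [lr_plan()].
#' @return an [lr_coefficients()] starting set.
#' @export
initialize_fit <- function(data, sys, plan = lr_plan()) {
  ex <- lr_expansion(sys, plan$caps)
  des <- lr_design(ex, data$geoms)
  tie <- .tie_map(ex, plan$fixed)
  thf <- .initialize_theta(data, ex, des, tie, plan)
  lr_coefficients(ex, as.numeric(tie$Tmat %*% thf + tie$offset))
}

.initialize_theta <- function(data, ex, des, tie, plan) {
  if (length(data) == 0L) stop("empty dataset")
  E <- data$energy
  far <- which(data$geoms$R >= stats::quantile(data$geoms$R,
                                               1 - plan$far_fraction))
  if (length(far) < 3L) far <- order(data$geoms$R, decreasing = TRUE)[
    seq_len(min(length(E), 3L))]
  orders <- sort(unique(ex$terms$order))
  thf <- stats::setNames(numeric(length(tie$free_names)), tie$free_names)
  if (length(orders) == 0L) { # asymptote only
    thf["E_asym"] <- mean(E[far])
    return(thf)
  }
  n2 <- if (length(orders) >= 2L) orders[2L] else orders[1L]

  ## regressors: intercept + lumped linear parameters of orders <= n2,
  ## built in symmetry-adapted coordinates (one column per allowed
  ## coordinate product, so symmetry-forbidden components never enter
  ## and the far-range solve stays well conditioned)
  basis_of <- function(side, l) {
    if (l == 0L) return(matrix(1, 1L, 1L))
    if (side == "A") ex$basisA[[as.character(l)]] else ex$basisB[[as.character(l)]]
  }
  cols <- list(intercept = rep(1, length(far)))
  meta <- list(list(kind = "intercept"))
  for (b in des$elec) {
    if (b$order > n2) next
    M <- des$M[[paste0(b$la, "_", b$lb)]][far, , drop = FALSE]
    BA <- basis_of("A", b$la); BB <- basis_of("B", b$lb)
    for (i in seq_len(ncol(BA))) for (j in seq_len(ncol(BB))) {
      cols[[length(cols) + 1L]] <- M %*% as.vector(outer(BA[, i], BB[, j]))
      meta[[length(meta) + 1L]] <- list(kind = "elec", la = b$la, lb = b$lb,
                                        i = i, j = j)
    }
  }
  ## induction lumps: one parameter per (side, block, pattern k,
  ## unordered source coordinate pair)
  ind_cols <- new.env(parent = emptyenv())
  ind_meta <- list()
  for (tm in des$ind) {
    if (tm$order > n2) next
    blk_key <- .block_key(tm$blk)
    pat <- if (tm$side == "A") ex$patA[[blk_key]] else ex$patB[[blk_key]]
    oth <- if (tm$side == "A") "B" else "A"
    n1 <- 2L * tm$la1 + 1L; n2b <- 2L * tm$la2 + 1L
    k1 <- if (tm$side == "A") paste0(tm$la1, "_", tm$lu1) else paste0(tm$lu1, "_", tm$la1)
    k2 <- if (tm$side == "A") paste0(tm$la2, "_", tm$lu2) else paste0(tm$lu2, "_", tm$la2)
    M1 <- des$M[[k1]][far, , drop = FALSE]
    M2 <- des$M[[k2]][far, , drop = FALSE]
    B1 <- basis_of(oth, tm$lu1); B2 <- basis_of(oth, tm$lu2)
    for (uc in seq_len(ncol(B1))) for (uc2 in seq_len(ncol(B2))) {
      T1 <- if (tm$side == "A") M1 %*% kronecker(B1[, uc], diag(n1))
            else M1 %*% kronecker(diag(n1), B1[, uc])
      T2 <- if (tm$side == "A") M2 %*% kronecker(B2[, uc2], diag(n2b))
            else M2 %*% kronecker(diag(n2b), B2[, uc2])
      for (k in seq_along(pat)) {
        Mk <- if (tm$tp) t(pat[[k]]) else pat[[k]]
        val <- -0.5 * rowSums((T1 %*% Mk) * T2)
        key <- paste(tm$side, blk_key, k,
                     paste(sort(c(paste(tm$lu1, uc), paste(tm$lu2, uc2))),
                           collapse = "|"), sep = ":")
        if (is.null(ind_cols[[key]])) {
          ind_cols[[key]] <- val
          ind_meta[[length(ind_meta) + 1L]] <-
            list(kind = "ind", key = key, side = tm$side, blk = blk_key,
                 k = k, lu1 = tm$lu1, uc1 = uc, lu2 = tm$lu2, uc2 = uc2)
        } else ind_cols[[key]] <- ind_cols[[key]] + val
      }
    }
  }
  for (m in ind_meta) cols[[length(cols) + 1L]] <- ind_cols[[m$key]]
  meta <- c(meta, ind_meta)
  d_use <- which(des$d_order <= n2)
  for (j in d_use) {
    cols[[length(cols) + 1L]] <- des$Fd[far, j]
    meta[[length(meta) + 1L]] <- list(kind = "disp",
                                      name = colnames(des$Fd)[j])
  }
  X <- do.call(cbind, cols)
  beta <- tryCatch(qr.coef(qr(X), E[far]), error = function(e) NULL)
  if (is.null(beta)) beta <- rep(0, ncol(X))
  beta[is.na(beta)] <- 0
  ## flat data carry no interaction signal: the numeric noise the linear
  ## solve leaves in the lumped products would be amplified by the
  ## square root of the rank-one factorization below, so zero it
  if (stats::sd(E[far]) <= 1e-13 * max(1, abs(mean(E[far])))) {
    beta[-1L] <- 0
    beta[1L] <- mean(E[far])
  }

  thf["E_asym"] <- beta[1L]
  ## electrostatic coordinate products -> per-molecule coordinates by
  ## the cascade (anchored at pinned charges where available)
  prods <- list()
  for (i in seq_along(meta)) {
    m <- meta[[i]]
    if (m$kind != "elec") next
    key <- paste0(m$la, "_", m$lb)
    if (is.null(prods[[key]]))
      prods[[key]] <- matrix(0, ncol(basis_of("A", m$la)),
                             ncol(basis_of("B", m$lb)))
    prods[[key]][m$i, m$j] <- beta[i]
  }
  qest <- .cascade_multipoles(ex, prods)
  for (l in names(qest$A)) {
    nm <- sprintf("QA.%s.%d", l, seq_along(qest$A[[l]]))
    hit <- nm %in% names(thf)
    thf[nm[hit]] <- qest$A[[l]][hit]
  }
  for (l in names(qest$B)) {
    nm <- sprintf("QB.%s.%d", l, seq_along(qest$B[[l]]))
    hit <- nm %in% names(thf)
    thf[nm[hit]] <- qest$B[[l]][hit]
  }
  ## induction lumps -> alpha coordinates given the moment estimates
  for (i in seq_along(meta)) {
    m <- meta[[i]]
    if (m$kind != "ind") next
    qsrc <- if (m$side == "A") qest$B else qest$A
    q1 <- qsrc[[as.character(m$lu1)]]; q2 <- qsrc[[as.character(m$lu2)]]
    if (is.null(q1) || is.null(q2)) next
    denom <- q1[m$uc1] * q2[m$uc2]
    nm <- sprintf("a%s.%s.%d", m$side, m$blk, m$k)
    if (nm %in% names(thf) && abs(denom) > 1e-10 && thf[nm] == 0)
      thf[nm] <- beta[i] / denom
  }
  for (i in seq_along(meta)) {
    m <- meta[[i]]
    if (m$kind == "disp" && m$name %in% names(thf)) thf[m$name] <- beta[i]
  }
  thf
}

## greedy cascade: resolve per-molecule multipole components from lumped
## products, anchored at pinned charges, else by rank-one factorization
.cascade_multipoles <- function(ex, prods) {
  sys <- ex$sys
  A <- list(); B <- list()
  if (sys$molA$charge != 0) A[["0"]] <- sys$molA$charge
  if (sys$molB$charge != 0) B[["0"]] <- sys$molB$charge
  keys <- names(prods)
  if (length(keys) == 0L) return(list(A = A, B = B))
  ord <- order(vapply(keys, function(k)
    sum(as.integer(strsplit(k, "_")[[1]])), numeric(1)))
  keys <- keys[ord]
  repeat {
    changed <- FALSE
    for (k in keys) {
      rl <- strsplit(k, "_")[[1]]
      la <- rl[1]; lb <- rl[2]
      P <- prods[[k]]
      qa <- A[[la]]; qb <- B[[lb]]
      if (!is.null(qa) && is.null(B[[lb]]) && sum(qa^2) > 1e-12) {
        B[[lb]] <- as.numeric(t(P) %*% qa) / sum(qa^2); changed <- TRUE
      } else if (!is.null(qb) && is.null(A[[la]]) && sum(qb^2) > 1e-12) {
        A[[la]] <- as.numeric(P %*% qb) / sum(qb^2); changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## no anchor resolved anything: factorize the leading block
  todo <- keys[vapply(keys, function(k) {
    rl <- strsplit(k, "_")[[1]]
    is.null(A[[rl[1]]]) && is.null(B[[rl[2]]])
  }, logical(1))]
  if (length(todo) > 0L) {
    k <- todo[1L]
    rl <- strsplit(k, "_")[[1]]
    sv <- svd(prods[[k]])
    if (sv$d[1L] > 1e-14) {
      s <- sqrt(sv$d[1L])
      u <- sv$u[, 1L] * s; v <- sv$v[, 1L] * s
      i0 <- which.max(abs(u))
      if (u[i0] < 0) { u <- -u; v <- -v }
      A[[rl[1]]] <- u; B[[rl[2]]] <- v
      ## rerun the cascade with the new anchor
      repeat {
        changed <- FALSE
        for (k2 in keys) {
          rl2 <- strsplit(k2, "_")[[1]]
          P <- prods[[k2]]
          qa <- A[[rl2[1]]]; qb <- B[[rl2[2]]]
          if (!is.null(qa) && is.null(B[[rl2[2]]]) && sum(qa^2) > 1e-12) {
            B[[rl2[2]]] <- as.numeric(t(P) %*% qa) / sum(qa^2); changed <- TRUE
          } else if (!is.null(qb) && is.null(A[[rl2[1]]]) && sum(qb^2) > 1e-12) {
            A[[rl2[1]]] <- as.numeric(P %*% qb) / sum(qb^2); changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
  }
  list(A = A, B = B)
}

#' Staged nonlinear least-squares fit of the expansion coefficients
#'
#' The central fitting function: assembles the symmetry-adapted expansion
#' of the system, initializes from the far long range (the asymptote is a
#' fitted coefficient, the data need not be zeroed), then introduces the
#' interaction terms order by order, refitting all active coefficients at
#' each stage with Levenberg--Marquardt least squares (warm-started, so
#' the training RMSE never increases across stages).  Exchange and fixed
#' coefficient constraints are honored exactly; when nothing pins the
#' overall sign, the leading multipole coordinate of molecule A is
#' oriented non-negative.
#'
#' @param data an [lr_dataset()].
#' @param system an [lr_system()].
#' @param caps final per-interaction caps (used when \code{plan} is not
#'   given).
#' @param plan an [lr_plan()]; overrides \code{caps}.
#' @param verbose print per-stage progress.
#' @param detect run [detect_outliers()] on the final fit.
#' @return an object of class \code{lr_fit} with components
#'   \code{coefficients} ([lr_coefficients()]), \code{history} (per-stage
#'   data frame), \code{residuals}, \code{data}, \code{plan} and
#'   \code{converged}.
#' @export
lr_fit <- function(data, system, caps = 6, plan = NULL, verbose = FALSE,
                   detect = TRUE) {
  stopifnot(inherits(data, "lr_dataset"), inherits(system, "lr_system"))
  if (is.null(plan)) plan <- lr_plan(caps)
  set.seed(plan$seed)
  ex <- lr_expansion(system, plan$caps)
  des <- lr_design(ex, data$geoms)
  tie <- .tie_map(ex, plan$fixed)
  act <- .par_activation(ex)
  stages <- if (is.null(plan$stages)) .default_stages(ex, plan$caps)
            else plan$stages
  E <- data$energy
  nfree_final <- sum(.active_free(act, tie, plan$caps))
  if (length(E) < nfree_final)
    stop("fewer points (", length(E), ") than free parameters (",
         nfree_final, ")")
  if (length(E) < 5L * nfree_final)
    warning("dataset has fewer than 5 points per free parameter (",
            length(E), " for ", nfree_final, ")")
  .warn_duplicates(data)

  thf <- .initialize_theta(data, ex, des, tie, plan)
  hist_rows <- list()
  conv_all <- TRUE
  for (si in seq_along(stages)) {
    cp <- stages[[si]]
    on <- .active_free(act, tie, cp)
    resid_fn <- function(par) {
      th <- thf; th[on] <- par
      .design_energy(des, as.numeric(tie$Tmat %*% th + tie$offset), cp) - E
    }
    ok <- TRUE
    if (sum(on) > 0L) {
      out <- minpack.lm::nls.lm(
        par = thf[on], fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = plan$ftol, ptol = plan$ptol,
          maxiter = min(plan$maxit, 1024L), maxfev = 100000L))
      start_rss <- sum(resid_fn(thf[on])^2)
      if (out$deviance <= start_rss) thf[on] <- out$par
      ok <- out$info %in% c(1L, 2L, 3L, 4L)
    }
    r <- resid_fn(thf[on])
    st <- fit_statistics(r, E)
    lead <- utils::head(grep("^Q", tie$free_names[on], value = TRUE), 3L)
    hist_rows[[si]] <- data.frame(
      stage = si, elec = cp[["elec"]], ind = cp[["ind"]], disp = cp[["disp"]],
      n_par = sum(on), rmse = st[["rmse"]], r2 = st[["r2"]],
      converged = ok,
      leading = paste(sprintf("%s=%.6g", lead, thf[lead]), collapse = " "),
      stringsAsFactors = FALSE)
    conv_all <- conv_all && ok
    if (verbose)
      message(sprintf("stage %d (caps %d/%d/%d): %d params, RMSE %.3e, R2 %.6f%s",
                      si, cp[["elec"]], cp[["ind"]], cp[["disp"]], sum(on),
                      st[["rmse"]], st[["r2"]], if (ok) "" else " [not converged]"))
  }
  ## gauge: orient the leading free multipole coordinate of A non-negative.
  ## Only neutral unanchored systems carry the sign gauge: a pinned charge
  ## or a fixed multipole already decides every sign physically.
  if (system$molA$charge == 0 && system$molB$charge == 0 &&
      !any(grepl("^Q", names(.resolve_fixed_safe(ex, plan$fixed))))) {
    qa <- grep("^QA\\.", tie$free_names)
    if (length(qa) > 0L) {
      lead <- qa[which(abs(thf[qa]) > 0)[1L]]
      if (!is.na(lead) && thf[lead] < 0) {
        qf <- grep("^Q[AB]\\.", tie$free_names)
        thf[qf] <- -thf[qf]
      }
    }
  }
  theta_full <- as.numeric(tie$Tmat %*% thf + tie$offset)
  cf <- lr_coefficients(ex, theta_full)
  res <- .design_energy(des, cf$theta, plan$caps) - E
  fit <- structure(list(coefficients = cf, theta_free = thf, tie = tie,
                        history = do.call(rbind, hist_rows),
                        residuals = res, data = data, system = system,
                        plan = plan, expansion = ex,
                        converged = conv_all),
                   class = "lr_fit")
  fit$outliers <- if (detect) detect_outliers(fit)
                  else rep(FALSE, length(res))
  fit
}

.resolve_fixed_safe <- function(ex, fixed) {
  if (is.null(fixed) || length(fixed) == 0L) return(list())
  .resolve_fixed(ex, fixed)
}

.warn_duplicates <- function(data) {
  key <- do.call(paste, c(lapply(data$geoms, function(x) sprintf("%.12g", x)),
                          sep = "|"))
  dup <- duplicated(key)
  if (any(dup)) {
    bad <- unique(key[dup])
    diff_e <- vapply(bad, function(k) {
      es <- data$energy[key == k]
      max(es) - min(es) > 0
    }, logical(1))
    if (any(diff_e))
      warning(sum(diff_e), " duplicate geometr",
              if (sum(diff_e) == 1) "y carries" else "ies carry",
              " differing energies; all points are kept")
  }
  invisible(NULL)
}

#' Outlier flags with relative-error weighting
#'
#' Weighted residuals \eqn{w_i = |r_i| / \max(|E_i - E_{asym}|,
#' \epsilon)} emphasize relative error, so the detector becomes more
#' sensitive at large \eqn{R} where the interaction is small;
#' \eqn{\epsilon} is \code{1e-3} of the dataset's interaction-energy
#' scale.  A point is flagged when its weight lies beyond \code{k} robust
#' scales (1.4826 MAD) above the median weight \emph{and} its raw
#' residual is itself beyond \code{k} robust scales of the residual
#' distribution -- the second condition keeps ordinary noise at the
#' far-range points (where any fixed noise level is a large relative
#' error) from being reported.  Because least squares is not robust, a
#' gross outlier distorts the fit it is judged against; absolute spikes
#' (beyond 10 robust scales) therefore trigger one trimmed refit and all
#' points are re-judged against the clean model.
#'
#' @param fit an [lr_fit()].
#' @param k flag threshold in robust scales (default 4).
#' @param refit allow the one-pass trimmed refit (default \code{TRUE}).
#' @return logical vector of flags (also stored as \code{fit$outliers}).
#' @export
detect_outliers <- function(fit, k = 4, refit = TRUE) {
  stopifnot(inherits(fit, "lr_fit"))
  res <- fit$residuals
  easym <- fit$coefficients$theta[["E_asym"]]
  ## a large outlier drags the (non-robust) least-squares fit and inflates
  ## every weighted residual; when absolute spikes are present, refit
  ## without them and judge all points against the clean model
  sr0 <- stats::mad(res, center = 0)
  cand <- sr0 > 0 & abs(res) > 10 * sr0
  if (refit && any(cand) && sum(cand) <= 0.1 * length(res)) {
    trimmed <- suppressWarnings(tryCatch(
      lr_fit(subset_dataset(fit$data, !cand), fit$system, plan = fit$plan,
             detect = FALSE),
      error = function(e) NULL))
    if (!is.null(trimmed)) {
      res <- predict(trimmed, fit$data$geoms) - fit$data$energy
      easym <- trimmed$coefficients$theta[["E_asym"]]
    }
  }
  inter <- abs(fit$data$energy - easym)
  eps <- 1e-3 * max(inter, 1e-300)
  w <- abs(res) / pmax(inter, eps)
  s <- stats::mad(w)
  sr <- stats::mad(res, center = 0)
  if (s == 0 || sr == 0) return(rep(FALSE, length(w)))
  (w > stats::median(w) + k * s) & (abs(res) > k * sr)
}

#' Histogram of fitting residuals
#'
#' @param fit an [lr_fit()].
#' @param bins number of bins (>= 1).
#' @return list with \code{counts}, \code{breaks} and \code{mids};
#'   \code{sum(counts)} equals the number of points.
#' @export
residual_histogram <- function(fit, bins = 30L) {
  stopifnot(inherits(fit, "lr_fit"))
  if (bins < 1L) stop("bins must be >= 1")
  r <- fit$residuals
  rng <- range(r)
  if (diff(rng) == 0) {
    return(list(counts = length(r), breaks = c(rng[1] - 0.5, rng[1] + 0.5),
                mids = rng[1]))
  }
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(r, breaks = br, plot = FALSE)
  list(counts = h$counts, breaks = h$breaks, mids = h$mids)
}

## ---- S3 model interface -------------------------------------------------

#' @export
print.lr_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<lr_fit> %s -- %s (%s)\n", x$system$molA$name,
              x$system$molB$name, x$system$relation))
  cat(sprintf("  %d points, %d stages, final caps %d/%d/%d\n",
              length(x$data), nrow(h), x$plan$caps[["elec"]],
              x$plan$caps[["ind"]], x$plan$caps[["disp"]]))
  cat(sprintf("  final RMSE %.4e hartree (%.4g cm-1), R2 %.6f%s\n",
              h$rmse[nrow(h)], h$rmse[nrow(h)] * lr_constants$hartree_cm1,
              h$r2[nrow(h)], if (x$converged) "" else "  [not converged]"))
  if (any(x$outliers)) cat("  flagged outliers:", sum(x$outliers), "\n")
  invisible(x)
}

#' @export
summary.lr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.lr_fit")
}

#' @export
print.summary.lr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nStage history (RMSE in hartree):\n")
  print(x$fit$history[, c("stage", "elec", "ind", "disp", "n_par", "rmse",
                          "r2", "converged")], row.names = FALSE)
  cat("\nCoefficients:\n")
  print(x$fit$coefficients)
  invisible(x)
}

#' @export
coef.lr_fit <- function(object, ...) object$coefficients$theta

#' @export
residuals.lr_fit <- function(object, ...) object$residuals

#' @export
fitted.lr_fit <- function(object, ...) object$data$energy + object$residuals

#' Predict expansion energies at new geometries
#'
#' @param object an [lr_fit()].
#' @param newdata a data frame of geometries (bohr / radians), a list of
#'   [dimer_geometry()], or an [lr_dataset()]; defaults to the training
#'   geometries.
#' @param ... unused.
#' @return numeric vector of energies (hartree).
#' @export
predict.lr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (inherits(newdata, "lr_dataset")) newdata <- newdata$geoms
  evaluate_energy(object$coefficients, newdata)
}

#' @export
simulate.lr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sigma <- sqrt(mean(object$residuals^2))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plots of a staged fit
#'
#' Left: staged RMSE (log scale) against stage, the order-by-order
#' convergence picture.  Right: histogram of final residuals, which for a
#' balanced fit is narrow and symmetric.
#'
#' @param x an [lr_fit()].
#' @param bins histogram bins.
#' @param ... unused.
#' @export
plot.lr_fit <- function(x, bins = 30L, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$history
  plot(h$stage, h$rmse, log = "y", type = "b", xlab = "stage",
       ylab = "RMSE (hartree)", main = "staged fit convergence")
  graphics::hist(x$residuals, breaks = bins, xlab = "residual (hartree)",
                 main = "final residuals")
  invisible(x)
}
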