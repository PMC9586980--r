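# Moment-structure SEM engine: diagonally weighted least squares on an
# (S, V) pair, where S is an estimated covariance matrix and V the sampling
# covariance of vech(S). Models are expressed in a small text grammar and
# fitted in RAM form: Sigma = F (I - A)^-1 Sram (I - A)^-T F^T.

#' Parse a structural model from the text grammar
#'
#' One statement per line (or `;`-separated). Operators:
#' \describe{
#'   \item{`F =~ x1 + x2 + x3`}{factor loadings (measurement model)}
#'   \item{`F ~ gene`}{regression of `F` on `gene`}
#'   \item{`x1 ~~ x2`}{(co)variance; `x1 ~~ x1` is a (residual) variance}
#' }
#' A term may be prefixed with `value@` to fix the parameter at `value`
#' (e.g. `F =~ 1@x1`, `F ~~ 1@F`), or with `label*` to name it; terms
#' sharing a label share one free parameter (equality constraint).
#' Every variable that has no explicit self-covariance statement receives a
#' free (residual) variance automatically.
#'
#' @param text Model syntax string.
#' @return A `data.frame` of parameter rows (class `tsem_model`).
#' @export
tsem_model <- function(text) {
  lines <- unlist(strsplit(text, "[;\n]"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (ln in lines) {
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
      else if (grepl("~~", ln, fixed = TRUE)) "~~"
      else if (grepl("~", ln, fixed = TRUE)) "~"
      else stop("cannot parse model line: ", ln)
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse model line: ", ln)
    lhs <- trimws(parts[1])
    for (term in trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])) {
      fixed <- NA_real_; label <- NA_character_; var <- term
      if (grepl("@", term, fixed = TRUE)) {
        bits <- strsplit(term, "@", fixed = TRUE)[[1]]
        fixed <- as.numeric(bits[1]); var <- trimws(bits[2])
        if (is.na(fixed)) stop("bad fixed value in term: ", term)
      } else if (grepl("*", term, fixed = TRUE)) {
        bits <- strsplit(term, "*", fixed = TRUE)[[1]]
        label <- trimws(bits[1]); var <- trimws(bits[2])
      }
      rows[[length(rows) + 1]] <- data.frame(
        lhs = lhs, op = op, rhs = var, label = label,
        free = is.na(fixed), value = fixed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tsem_model", class(out))
  out
}

# Internal: resolve a parsed model against observed-variable names.
# Returns RAM skeleton: variable list, parameter table with matrix positions,
# free-parameter label map.
.build_ram <- function(model, obs) {
  latents <- setdiff(unique(model$lhs[model$op == "=~"]), obs)
  allvars <- c(obs, latents)
  unknown <- setdiff(unique(c(model$lhs, model$rhs)), allvars)
  if (length(unknown))
    stop("model mentions variables not in S or declared as latent: ",
         paste(unknown, collapse = ", "))

  # auto-add free residual variances
  has_var <- function(v) any(model$op == "~~" & model$lhs == v & model$rhs == v)
  for (v in allvars) if (!has_var(v))
    model <- rbind(model, data.frame(lhs = v, op = "~~", rhs = v,
                                     label = NA, free = TRUE, value = NA))

  idx <- function(v) match(v, allvars)
  model$mat <- ifelse(model$op == "~~", "S", "A")
  model$row <- ifelse(model$op == "=~", idx(model$rhs), idx(model$lhs))
  model$col <- ifelse(model$op == "=~", idx(model$lhs), idx(model$rhs))

  auto <- is.na(model$label)
  model$label[auto] <- paste0(model$lhs[auto], model$op[auto], model$rhs[auto])
  if (anyDuplicated(model$label[model$free])) {
    # equality constraints via shared labels are legitimate; duplicated
    # auto-labels (same statement twice) are not
    dup <- duplicated(paste(model$label, model$mat, model$row, model$col)) &
      model$free
    model <- model[!dup, , drop = FALSE]
  }
  free_labels <- unique(model$label[model$free])
  list(model = model, vars = allvars, obs = obs, latents = latents,
       free_labels = free_labels)
}

# Internal: start values per the package's fixed rule -- loadings
# 0.4*sqrt(mean diag S), residual variances 0.5*diag S (0.5*mean diag for
# latents), regressions and covariances 0.
.start_values <- function(ram, S) {
  md <- mean(diag(S))
  th <- numeric(length(ram$free_labels))
  names(th) <- ram$free_labels
  m <- ram$model
  for (lab in ram$free_labels) {
    row <- m[m$free & m$label == lab, , drop = FALSE][1, ]
    th[lab] <- if (row$op == "=~") 0.4 * sqrt(md)
      else if (row$op == "~") 0
      else if (row$lhs == row$rhs) {
        v <- row$lhs
        if (v %in% ram$obs) 0.5 * S[v, v] else 0.5 * md
      } else 0
  }
  th
}

# Internal: fill A and Sram from a parameter vector, return model-implied
# covariance of the observed variables plus the pieces needed downstream.
.implied <- function(ram, theta) {
  nv <- length(ram$vars)
  A <- matrix(0, nv, nv)
  Sr <- matrix(0, nv, nv)
  m <- ram$model
  vals <- ifelse(m$free, theta[m$label], m$value)
  for (i in seq_len(nrow(m))) {
    if (m$mat[i] == "A") A[m$row[i], m$col[i]] <- vals[i]
    else { Sr[m$row[i], m$col[i]] <- vals[i]; Sr[m$col[i], m$row[i]] <- vals[i] }
  }
  B <- solve(diag(nv) - A)
  E <- B %*% Sr %*% t(B)
  no <- length(ram$obs)
  Sigma <- E[seq_len(no), seq_len(no), drop = FALSE]
  dimnames(Sigma) <- list(ram$obs, ram$obs)
  list(Sigma = Sigma, A = A, Sr = Sr, B = B, E = E)
}

# Internal: analytic Jacobian d vech(Sigma) / d theta' (p* x q).
.jacobian <- function(ram, imp) {
  no <- length(ram$obs)
  B <- imp$B; E <- imp$E
  m <- ram$model
  q <- length(ram$free_labels)
  J <- matrix(0, no * (no + 1) / 2, q)
  low <- lower.tri(matrix(0, no, no), diag = TRUE)
  for (t in seq_len(q)) {
    lab <- ram$free_labels[t]
    rows <- which(m$free & m$label == lab)
    dS <- matrix(0, nrow(B), ncol(B))
    for (ri in rows) {
      i <- m$row[ri]; j <- m$col[ri]
      if (m$mat[ri] == "A") {
        # dSigma = B dA E + (B dA E)'
        term <- B[, i] %o% E[j, ]
        dS <- dS + term + t(term)
      } else {
        # dSigma = B dSr B'; dSr has a 1 at (i,j) and, when i != j, at (j,i)
        term <- B[, i] %o% B[, j]
        dS <- dS + term
        if (i != j) dS <- dS + t(term)
      }
    }
    J[, t] <- dS[seq_len(no), seq_len(no)][low]
  }
  J
}

#' Fit a moment-structure model by diagonally weighted least squares
#'
#' Minimizes `F(theta) = r' W r` with `r = vech(S) - vech(Sigma(theta))` and
#' `W = diag(V)^-1`, using a damped Gauss-Newton iteration with analytic
#' derivatives (deterministic given inputs and start values; relative
#' tolerance 1e-10, at most 500 iterations). Standard errors are sandwich
#' corrected: `(D'WD)^-1 D'W V W D (D'WD)^-1` with `D` the Jacobian of the
#' implied moments at the solution.
#'
#' @param S Estimated covariance matrix (symmetric, with dimnames).
#' @param V Sampling covariance matrix of `vech(S)`; must be positive
#'   semi-definite (smooth first with [smooth_nearest_psd()] if needed).
#' @param model Model syntax string or a parsed [tsem_model()].
#' @param max_iter,tol Gauss-Newton iteration cap and relative tolerance.
#' @return Object of class `tsem_fit`: estimates, sandwich `vcov` and SEs,
#'   residuals, model chi-square (`chisq`, `df`, `p`), convergence flag.
#' @export
fit_dwls <- function(S, V, model, max_iter = 500, tol = 1e-10) {
  if (is.character(model)) model <- tsem_model(model)
  obs <- rownames(S)
  if (is.null(obs)) stop("'S' must have dimnames")
  ram <- .build_ram(model, obs)
  p_star <- nrow(S) * (nrow(S) + 1) / 2
  if (nrow(V) != p_star) stop("V dimension does not match vech(S)")
  s_obs <- vech(S)
  W <- 1 / pmax(diag(V), .Machine$double.eps)

  theta <- .start_values(ram, S)
  imp <- .implied(ram, theta)
  r <- s_obs - vech(imp$Sigma)
  F0 <- sum(W * r * r)
  damp <- 1e-8
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    J <- .jacobian(ram, imp)
    WJ <- J * W
    H <- crossprod(J, WJ)
    g <- crossprod(WJ, r)
    ok_step <- FALSE
    for (tries in 1:40) {
      Hd <- H + damp * diag(pmax(diag(H), 1e-12), nrow(H))
      delta <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (is.null(delta)) { damp <- damp * 10; next }
      th_new <- theta + as.vector(delta)
      names(th_new) <- names(theta)
      imp_new <- tryCatch(.implied(ram, th_new), error = function(e) NULL)
      if (is.null(imp_new)) { damp <- damp * 10; next }
      r_new <- s_obs - vech(imp_new$Sigma)
      F1 <- sum(W * r_new * r_new)
      if (is.finite(F1) && F1 <= F0 + 1e-14 * (1 + F0)) {
        ok_step <- TRUE; break
      }
      damp <- damp * 10
    }
    if (!ok_step) break
    step_size <- max(abs(th_new - theta) / pmax(abs(theta), 1e-4))
    rel_drop <- (F0 - F1) / (F0 + 1e-300)
    theta <- th_new; imp <- imp_new; r <- r_new
    conv_now <- step_size < tol || (F0 > 0 && rel_drop < tol) || F1 < 1e-28
    F0 <- F1
    damp <- max(damp / 5, 1e-12)
    if (conv_now) { converged <- TRUE; break }
  }

  J <- .jacobian(ram, imp)
  WJ <- J * W
  H <- crossprod(J, WJ)
  Hinv <- tryCatch(solve(H), error = function(e) {
    warning("Jacobian rank-deficient at the solution; model may be ",
            "under-identified"); MASS::ginv(H)
  })
  vcov_sand <- Hinv %*% crossprod(WJ, V %*% WJ) %*% Hinv
  dimnames(vcov_sand) <- list(ram$free_labels, ram$free_labels)
  se <- sqrt(pmax(diag(vcov_sand), 0))

  fit <- structure(list(
    estimates = theta, se = se, vcov = vcov_sand,
    residuals = r, fmin = F0, converged = converged, iterations = iter,
    S = S, V = V, W = W, J = J, ram = ram, Sigma = imp$Sigma,
    obs = obs), class = "tsem_fit")
  cs <- model_chisq(fit)
  fit$chisq <- cs[["chisq"]]; fit$df <- cs[["df"]]; fit$p <- cs[["p"]]
  fit$log_p <- attr(cs, "log_p")
  fit
}

#' Residual-based model chi-square
#'
#' Computes `T = r' U r` where `U` is a generalized inverse of the sampling
#' covariance of the residual moment vector under the fitted model,
#' `V_r = A V A'` with `A = I - D (D'WD)^-1 D'W`. The computation is carried
#' out in the SE-standardized metric (each moment divided by its sampling
#' SE) for numerical stability; degrees of freedom are the numerical rank of
#' the standardized `V_r`. Under a correctly specified model `T` is
#' chi-square distributed with `df` degrees of freedom.
#'
#' @param fit A `tsem_fit` object.
#' @param V Optional sampling covariance overriding the one stored in `fit`.
#' @return Named vector `c(chisq, df, p)` with attribute `log_p` (natural
#'   log of the p-value, for downstream quantile transforms at extreme
#'   significance).
#' @export
model_chisq <- function(fit, V = NULL) {
  if (is.null(V)) V <- fit$V
  p_star <- length(fit$residuals)
  d <- sqrt(pmax(diag(V), .Machine$double.eps))
  rs <- fit$residuals / d
  Js <- fit$J / d
  Vs <- V / (d %o% d)
  q <- ncol(Js)
  df_nominal <- p_star - q
  if (df_nominal <= 0 || sum(rs * rs) < 1e-20) {
    out <- c(chisq = 0, df = max(df_nominal, 0), p = 1)
    attr(out, "log_p") <- 0
    return(out)
  }
  # W in the standardized metric is the identity (W = diag(V)^-1 unscaled)
  H <- crossprod(Js)
  Hinv <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  Amat <- diag(p_star) - Js %*% Hinv %*% t(Js)
  Vr <- Amat %*% Vs %*% t(Amat)
  e <- eigen(force_symmetric(Vr), symmetric = TRUE)
  keep <- e$values > 1e-8 * max(e$values)
  df <- sum(keep)
  U <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  T_stat <- max(as.numeric(t(rs) %*% U %*% rs), 0)
  log_p <- stats::pchisq(T_stat, df, lower.tail = FALSE, log.p = TRUE)
  out <- c(chisq = T_stat, df = df, p = exp(log_p))
  attr(out, "log_p") <- log_p
  out
}

#' Evaluate a derived ("ghost") parameter with a delta-method SE
#'
#' The expression is any differentiable function of the model's free
#' parameter labels, evaluated at the estimates; its standard error comes
#' from the delta method using the sandwich covariance of the estimates.
#'
#' @param fit A `tsem_fit` object.
#' @param expression Character expression in the parameter labels, e.g.
#'   `"(bg * s2 * bp) / (bg * s2 * bp + ru)"`. Constants may be included.
#' @param extra Optional named list of constants used by the expression.
#' @return Named vector `c(value, se)`.
#' @export
ghost_parameter <- function(fit, expression, extra = list()) {
  expr <- parse(text = expression)
  est <- as.list(fit$estimates)
  env <- c(est, extra)
  value <- eval(expr, env)
  if (!is.finite(value)) stop("ghost parameter is undefined at the estimates")
  labs <- names(fit$estimates)
  grad <- numeric(length(labs))
  for (i in seq_along(labs)) {
    h <- 1e-6 * max(1, abs(fit$estimates[i]))
    up <- env; up[[labs[i]]] <- fit$estimates[i] + h
    dn <- env; dn[[labs[i]]] <- fit$estimates[i] - h
    vu <- eval(expr, up); vd <- eval(expr, dn)
    if (!is.finite(vu) || !is.finite(vd))
      stop("ghost parameter is not differentiable at the estimates")
    grad[i] <- (vu - vd) / (2 * h)
  }
  se <- sqrt(max(as.numeric(t(grad) %*% fit$vcov %*% grad), 0))
  c(value = value, se = se)
}

#' @export
print.tsem_fit <- function(x, ...) {
  cat("DWLS moment-structure fit\n")
  cat(sprintf("  converged: %s after %d iterations (F = %.3e)\n",
              x$converged, x$iterations, x$fmin))
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 6))
  cat(sprintf("  model chi-square %.4f on %d df (p = %.3g)\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
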