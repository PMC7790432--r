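# Canonical correspondence analysis with permutation significance tests and
# significance-then-criterion forward selection of environmental constraints.
#
# The decomposition follows the classical chi-square formulation: the count
# table is turned into the matrix of standardized chi-square residuals, that
# matrix is projected (row-weighted) onto the constraint space, and the
# projection is decomposed by SVD. Total inertia is then the squared
# Frobenius norm of the residual matrix and splits exactly (Pythagoras) into
# a constrained and an unconstrained part.

#' Chi-square residual transform of a count table
#'
#' For `p = counts / grand_total` with row margins `r` and column margins
#' `c`, returns `q_ij = (p_ij - r_i c_j) / sqrt(r_i c_j)` together with the
#' margins. `sum(q^2) * grand_total` is the classical chi-square statistic of
#' the table, and `sum(q^2)` is the total inertia of correspondence analysis.
#'
#' @param counts numeric matrix, samples x taxa, non-negative, no all-zero
#'   row or column.
#' @return list with `q` (matrix), `row_weights` (`r`), `col_weights` (`c`),
#'   `grand_total`.
#' @export
chi_square_residuals <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0)) {
    bad <- which(rs == 0)[1]
    stop_validation("all-zero sample row: ",
                    rownames(counts)[bad] %||% as.character(bad))
  }
  if (any(cs == 0)) {
    bad <- which(cs == 0)[1]
    stop_validation("all-zero taxon column: ",
                    colnames(counts)[bad] %||% as.character(bad))
  }
  tot <- sum(counts)
  p <- counts / tot
  r <- rowSums(p); c <- colSums(p)
  q <- (p - outer(r, c)) / sqrt(outer(r, c))
  list(q = q, row_weights = r, col_weights = c, grand_total = tot)
}

# weighted centering + row scaling of a constraint matrix, shared by the fit
# and the permutation loop
weight_constraints <- function(X, r) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colSums(X * r), "-")
  Xc * sqrt(r)
}

# fast inner projection: constrained inertia and rank for given residual
# matrix q and pre-weighted constraints
cca_core <- function(q, Xw) {
  QR <- qr(Xw)
  fitted <- qr.fitted(QR, q)
  list(constrained = sum(fitted^2), rank = QR$rank, QR = QR, fitted = fitted)
}

#' Fit a canonical correspondence analysis
#'
#' Constrains the chi-square residual structure of `counts` by the columns
#' of `constraints` (numeric; expand categorical variables to indicator
#' columns first, e.g. with [expand_constraints()]). Collinear constraint
#' columns are dropped with a warning and reported as `aliased`.
#'
#' @param counts samples x taxa count (or relative abundance) matrix.
#' @param constraints samples x variables numeric matrix or data.frame,
#'   complete cases only.
#' @return object of class `cca_model` with elements `eigenvalues`,
#'   `total_inertia`, `constrained_inertia`, `residual_inertia`,
#'   `site_scores` (linear-combination scores), `species_scores`,
#'   `biplot_scores`, `constraint_names`, `aliased`, `q_df` (constrained
#'   degrees of freedom), `n_samples`, `row_weights`, `col_weights`.
#' @export
cca_fit <- function(counts, constraints) {
  counts <- as.matrix(counts)
  X <- as.matrix(constraints)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) != nrow(counts))
    stop_validation("constraints must have one row per sample")
  if (anyNA(X))
    stop_validation("constraints must be complete-case (no missing values)")
  if (nrow(counts) <= ncol(X) + 1)
    warning("fewer samples than constraints + 1; model is saturated")
  cr <- chi_square_residuals(counts)
  Xw <- weight_constraints(X, cr$row_weights)
  core <- cca_core(cr$q, Xw)
  aliased <- character()
  if (core$rank < ncol(Xw)) {
    aliased <- colnames(X)[core$QR$pivot[(core$rank + 1):ncol(Xw)]]
    warning("collinear constraints dropped: ", paste(aliased, collapse = ", "))
  }
  total <- sum(cr$q^2)
  constrained <- core$constrained
  sv <- svd(core$fitted)
  keep <- which(sv$d^2 > max(1e-12, 1e-10 * max(sv$d^2, 1)))
  keep <- utils::head(keep, core$rank)
  eig <- sv$d[keep]^2
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  site <- sweep(u, 1, sqrt(cr$row_weights), "/")
  species <- sweep(v, 1, sqrt(cr$col_weights), "/")
  # biplot scores: weighted correlation of each constraint with the
  # constrained axes (unit-normalized weighted constraint columns vs u)
  Xn <- sweep(Xw, 2, sqrt(colSums(Xw^2)), "/")
  biplot <- crossprod(Xn, u)
  if (length(eig)) {
    axis_names <- paste0("CCA", seq_along(eig))
    dimnames(site) <- list(rownames(counts), axis_names)
    dimnames(species) <- list(colnames(counts), axis_names)
    dimnames(biplot) <- list(colnames(X), axis_names)
  }
  structure(list(
    eigenvalues = eig,
    total_inertia = total,
    constrained_inertia = constrained,
    residual_inertia = total - constrained,
    site_scores = site,
    species_scores = species,
    biplot_scores = biplot,
    constraint_names = colnames(X),
    aliased = aliased,
    q_df = core$rank,
    n_samples = nrow(counts),
    row_weights = cr$row_weights,
    col_weights = cr$col_weights),
    class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf(paste0("cca_model: %d samples, %d constrained df\n",
                     "  inertia: total %.4f = constrained %.4f (%.1f%%) + residual %.4f\n"),
              x$n_samples, x$q_df, x$total_inertia, x$constrained_inertia,
              100 * x$constrained_inertia / x$total_inertia,
              x$residual_inertia))
  if (length(x$eigenvalues))
    cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

# pseudo-F for given inertia split
pseudo_f_stat <- function(constrained, residual, n, q_df) {
  (constrained / q_df) / (residual / (n - q_df - 1))
}

#' Permutation significance test for CCA constraints
#'
#' ANOVA-like test: the pseudo-F statistic
#' `(constrained/q_df) / (residual/(n - q_df - 1))` of the observed model is
#' compared with its distribution under random row permutations of the
#' constraint matrix; `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. With
#' `margin = "variable"` the additional contribution of `variable` on top of
#' the remaining constraints is tested by permuting only that variable's
#' rows (a marginal added-term test, used during forward selection).
#'
#' @param counts samples x taxa table.
#' @param constraints samples x variables numeric matrix.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; the permutation stream is reproducible.
#' @param margin `"whole"` (default) or `"variable"`.
#' @param variable column name(s) tested when `margin = "variable"`
#'   (a categorical variable's indicator block is permuted jointly).
#' @return list with `p_value`, `pseudo_f`, `n_perm`, `margin`.
#' @export
permutation_test <- function(counts, constraints, n_perm = 199, seed = 1,
                             margin = c("whole", "variable"), variable = NULL) {
  margin <- match.arg(margin)
  if (n_perm < 99) stop_validation("n_perm must be at least 99")
  counts <- as.matrix(counts)
  X <- as.matrix(constraints)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  cr <- chi_square_residuals(counts)
  q <- cr$q; r <- cr$row_weights
  n <- nrow(counts)
  total <- sum(q^2)
  if (margin == "whole") {
    obs_core <- cca_core(q, weight_constraints(X, r))
    f_obs <- pseudo_f_stat(obs_core$constrained, total - obs_core$constrained,
                           n, obs_core$rank)
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      Xp <- X[sample.int(n), , drop = FALSE]
      core <- cca_core(q, weight_constraints(Xp, r))
      pseudo_f_stat(core$constrained, total - core$constrained, n, core$rank)
    }, numeric(1)))
  } else {
    if (is.null(variable) || !all(variable %in% colnames(X)))
      stop_validation("margin='variable' needs 'variable' columns present in constraints")
    other <- setdiff(colnames(X), variable)
    base_core <- if (length(other))
      cca_core(q, weight_constraints(X[, other, drop = FALSE], r))
    else list(constrained = 0, rank = 0L)
    partial_f <- function(Xfull) {
      core <- cca_core(q, weight_constraints(Xfull, r))
      df_add <- max(core$rank - base_core$rank, 1L)
      ((core$constrained - base_core$constrained) / df_add) /
        ((total - core$constrained) / (n - core$rank - 1))
    }
    f_obs <- partial_f(X)
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      Xp <- X
      Xp[, variable] <- Xp[sample.int(n), variable]
      partial_f(Xp)
    }, numeric(1)))
  }
  list(p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       pseudo_f = f_obs, n_perm = n_perm, margin = margin)
}

#' Deviance-style information criterion for a CCA model
#'
#' `n * log(residual_inertia / n) + 2 * (q_df + 1)` with `n` the number of
#' samples and `q_df` the constrained degrees of freedom: a pseudo-AIC that
#' rewards explained inertia and charges 2 per constraint dimension, used as
#' the tie-break among equally significant candidates during forward
#' selection. Lower is better; a saturated model with zero residual inertia
#' is degenerate and returns `-Inf` with a warning.
#'
#' @param model a `cca_model`, or a list with `residual_inertia`,
#'   `n_samples`, `q_df`.
#' @return criterion value (scalar).
#' @export
pseudo_aic <- function(model) {
  res <- model$residual_inertia
  n <- model$n_samples
  q_df <- model$q_df
  if (res <= 0) {
    warning("zero residual inertia: criterion degenerate (-Inf)")
    return(-Inf)
  }
  n * log(res / n) + 2 * (q_df + 1)
}

#' Expand an environmental data frame to numeric constraint columns
#'
#' Numeric columns pass through; factors/characters become indicator
#' columns dropping the reference level (first factor level; `Winter` for
#' [assign_season()] output ordered Spring, Summer, Autumn, Winter is set as
#' reference explicitly by callers that want it). A two-level `tide` column
#' becomes a single `tidelow`/`tidehigh` indicator.
#'
#' @param env `data.frame` of candidate variables (rows = samples).
#' @param reference named list mapping column names to the level used as
#'   reference (dropped) for categorical columns.
#' @return list with `matrix` (numeric, one row per sample, NA preserved)
#'   and `blocks` (named list mapping each original variable to its column
#'   names in the matrix).
#' @export
expand_constraints <- function(env, reference = list(season = "Winter")) {
  cols <- list(); blocks <- list()
  for (nm in names(env)) {
    v <- env[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      blocks[[nm]] <- nm
    } else {
      f <- if (is.factor(v)) v else factor(v)
      ref <- reference[[nm]] %||% levels(f)[1]
      lev <- setdiff(levels(f), ref)
      if (!length(lev)) {
        warning("constant categorical variable dropped: ", nm)
        next
      }
      m <- vapply(lev, function(L) as.numeric(f == L), numeric(length(f)))
      m <- matrix(m, nrow = length(f),
                  dimnames = list(NULL, paste0(nm, lev)))
      m[is.na(v), ] <- NA_real_
      cols[[nm]] <- m
      blocks[[nm]] <- colnames(m)
    }
  }
  list(matrix = do.call(cbind, cols), blocks = blocks)
}

#' Forward selection of environmental constraints
#'
#' Implements significance-then-criterion selection: at each step every
#' unselected candidate is added to the current model and tested with a
#' marginal permutation test; among candidates with `p < alpha` the one with
#' the lowest [pseudo_aic()] enters; selection stops when no candidate is
#' significant. Samples with a missing value in any candidate are dropped
#' first (complete-case analysis) and the dropped count is reported.
#'
#' @param counts samples x taxa table (rows aligned with `env`).
#' @param env `data.frame` of candidate variables; categorical columns are
#'   expanded via [expand_constraints()] and enter/leave as one block.
#' @param alpha significance level for entry (default 0.05).
#' @param n_perm permutations per test (default 199).
#' @param seed integer seed controlling the whole permutation stream.
#' @param reference reference levels for categorical candidates.
#' @return list of class `selection_trace` with `trace` (`data.frame`: step,
#'   candidate, p_value, criterion, selected), `selected` (character, in
#'   entry order), `model` (final `cca_model`, or `NULL` if nothing
#'   selected), `n_samples_used`, `n_samples_dropped`.
#' @export
forward_select <- function(counts, env, alpha = 0.05, n_perm = 199, seed = 1,
                           reference = list(season = "Winter")) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(env))
    stop_validation("counts and env must have the same number of rows")
  ex <- expand_constraints(env, reference)
  X <- ex$matrix
  cc <- stats::complete.cases(X)
  n_dropped <- sum(!cc)
  X <- X[cc, , drop = FALSE]
  counts_cc <- counts[cc, , drop = FALSE]
  counts_cc <- counts_cc[, colSums(counts_cc) > 0, drop = FALSE]
  candidates <- names(ex$blocks)
  selected <- character()
  trace <- list()
  step <- 0L
  # one deterministic sub-seed per evaluation, derived from the base seed
  eval_seed <- function(step, k)
    as.integer((as.numeric(seed) * 1000 + step * 100 + k) %% 2147483647)
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    evals <- data.frame(candidate = remaining, p_value = NA_real_,
                        criterion = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_along(remaining)) {
      cand <- remaining[k]
      colsel <- unlist(ex$blocks[c(selected, cand)], use.names = FALSE)
      Xtry <- X[, colsel, drop = FALSE]
      pt <- permutation_test(counts_cc, Xtry, n_perm = n_perm,
                             seed = eval_seed(step, k),
                             margin = "variable",
                             variable = ex$blocks[[cand]])
      fit <- suppressWarnings(cca_fit(counts_cc, Xtry))
      evals$p_value[k] <- pt$p_value
      evals$criterion[k] <- pseudo_aic(fit)
    }
    sig <- which(evals$p_value < alpha)
    pick <- if (length(sig)) sig[which.min(evals$criterion[sig])] else NA_integer_
    evals$selected <- seq_len(nrow(evals)) %in% pick
    evals$step <- step
    trace[[step]] <- evals
    if (is.na(pick)) break
    selected <- c(selected, evals$candidate[pick])
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(candidate = character(), p_value = numeric(),
               criterion = numeric(), selected = logical(), step = integer())
  trace_df <- trace_df[, c("step", "candidate", "p_value", "criterion", "selected")]
  final <- if (length(selected)) {
    suppressWarnings(
      cca_fit(counts_cc, X[, unlist(ex$blocks[selected], use.names = FALSE),
                           drop = FALSE]))
  } else NULL
  structure(list(trace = trace_df, selected = selected, model = final,
                 n_samples_used = sum(cc), n_samples_dropped = n_dropped),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("forward selection: %d sample(s) used (%d dropped incomplete)\n",
              x$n_samples_used, x$n_samples_dropped))
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
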