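# Fisher discriminant analysis of germination period (early / mesophytic /
# late) from cultivar-mean indicator vectors, plus the fixed published
# two-function reference model for the 15 canonical indicators.

# The 15 indicators the germination discriminant uses.  `b` is the blue
# pseudo-RGB colour mean and `L` the CIELab lightness L*; `sigma`, `S` and
# `G_lbp` are LBP histogram statistics (`G_lbp` is the LBP energy, named to
# stay distinct from the green band mean `G`).
GERMINATION_VARIABLES <- c("h", "s", "r", "b", "L", "Asm", "Var", "Hom",
                           "Dis", "sigma", "S", "G_lbp", "RVI", "DVI", "VOG")

# Published two-function discriminant: 15 coefficient pairs and the three
# class-centre projections, kept verbatim as a fixed reference model.
PRINTED_GERMINATION_COEF <- cbind(
  Y1 = c(h = -4.876, s = 9.114, r = -18.636, b = 12.217, L = -3.143,
         Asm = -5.471, Var = -3.089, Hom = -16.540, Dis = 14.565,
         sigma = -2.819, S = 5.969, G_lbp = 15.693, RVI = 0.101,
         DVI = -0.244, VOG = 3.937),
  Y2 = c(h = 3.941, s = 7.469, r = 12.911, b = -8.468, L = -2.090,
         Asm = -4.088, Var = -3.011, Hom = 7.450, Dis = -5.551,
         sigma = 4.832, S = -3.818, G_lbp = -1.803, RVI = 3.083,
         DVI = -6.684, VOG = 6.749))

PRINTED_GERMINATION_CENTERS <- rbind(
  early = c(Y1 = 0.353, Y2 = -2.845),
  mesophytic = c(Y1 = -7.907, Y2 = 0.984),
  late = c(Y1 = 4.721, Y2 = 1.163))

#' The published germination discriminant (fixed reference model)
#'
#' @return list with the 15x2 coefficient matrix (`coefficients`), the 3x2
#'   class-centre projections (`centers`) and the variable names.
#' @export
printed_germination_model <- function() {
  list(coefficients = PRINTED_GERMINATION_COEF,
       centers = PRINTED_GERMINATION_CENTERS,
       variables = GERMINATION_VARIABLES)
}

#' Per-cultivar mean indicator vectors
#'
#' Arithmetic mean of the requested indicators per cultivar (one row per
#' cultivar), with the germination stage attached from the table.
#'
#' @param table a [feature_table()] with germination labels.
#' @param variables indicator names (default the 15 canonical germination
#'   indicators).
#' @return list with `means` (cultivars x variables matrix) and `stages`
#'   (character vector per row).
#' @export
cultivar_means <- function(table, variables = GERMINATION_VARIABLES) {
  X <- feature_matrix(table, variables)
  cultivars <- unique(table$cultivar)
  M <- matrix(NA_real_, length(cultivars), length(variables),
              dimnames = list(cultivars, variables))
  stages <- character(length(cultivars))
  for (i in seq_along(cultivars)) {
    rows <- table$cultivar == cultivars[i]
    M[i, ] <- colMeans(X[rows, , drop = FALSE])
    st <- unique(table$germination[rows])
    stages[i] <- st[1]
  }
  list(means = M, stages = stages)
}

#' Fit a Fisher discriminant of germination stage
#'
#' Standardises X (column z-scores), forms the within- and between-class
#' scatter matrices, and solves the generalised eigenproblem
#' \eqn{S_b w = \lambda (S_w + \gamma I) w}, keeping the two leading axes
#' (at most `classes - 1`).  With as many variables as observations
#' \eqn{S_w} is near-singular, so a ridge \eqn{\gamma} (default
#' `1e-3 tr(S_w)/p`) conditions the solve; `regularization = 0` recovers
#' the classical solution when \eqn{S_w} is invertible.
#'
#' @param X numeric matrix (rows = observations, e.g. cultivar means).
#' @param stages class label per row (`early`/`mesophytic`/`late` or any
#'   factor with >= 2 levels).
#' @param regularization ridge added to the within-class scatter
#'   (`"auto"` for `1e-3 tr(S_w)/p`, or a nonnegative number).
#' @param standardize z-score the columns first (default TRUE).
#' @return object of class `discriminant_model`: `coefficients` (p x A, on
#'   the standardised scale), `centers` (class-mean projections),
#'   `eigenvalues`, the standardisation parameters, class `levels` and the
#'   training `projection`.
#' @export
fit_fisher <- function(X, stages, regularization = "auto", standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  f <- if (all(unique(stages) %in% GERMINATION_STAGES))
    factor(stages, levels = GERMINATION_STAGES[GERMINATION_STAGES %in% stages])
  else factor(stages)
  if (any(base::table(f) < 1) || nlevels(f) < 2)
    stopf("fit_fisher needs >= 2 non-empty classes")
  if (n < nlevels(f) + 1) stopf("too few observations (%d) to fit", n)
  mu <- colMeans(X)
  sg <- if (standardize) apply(X, 2, stats::sd) else rep(1, p)
  sg[sg < 1e-12] <- 1
  if (!standardize) mu <- rep(0, p)
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  grand <- colMeans(Z)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in levels(f)) {
    rows <- f == cl
    nk <- sum(rows)
    mk <- colMeans(Z[rows, , drop = FALSE])
    D <- sweep(Z[rows, , drop = FALSE], 2, mk)
    Sw <- Sw + crossprod(D)
    Sb <- Sb + nk * tcrossprod(mk - grand)
  }
  gamma <- if (identical(regularization, "auto"))
    1e-3 * sum(diag(Sw)) / p else as.numeric(regularization)
  stopifnot(gamma >= 0)
  A_max <- min(nlevels(f) - 1L, p)
  eg <- eigen(solve(Sw + gamma * diag(p), Sb))
  vals <- Re(eg$values)[seq_len(A_max)]
  W <- Re(eg$vectors)[, seq_len(A_max), drop = FALSE]
  # fix an overall sign: largest-|loading| coefficient positive per axis
  for (a in seq_len(ncol(W))) {
    k <- which.max(abs(W[, a]))
    if (W[k, a] < 0) W[, a] <- -W[, a]
  }
  rownames(W) <- colnames(X)
  colnames(W) <- paste0("Y", seq_len(ncol(W)))
  # scores are centred at the grand mean: it projects to the origin
  proj <- sweep(Z %*% W, 2, as.vector(grand %*% W))
  centers <- do.call(rbind, lapply(levels(f), function(cl)
    colMeans(proj[f == cl, , drop = FALSE])))
  rownames(centers) <- levels(f)
  structure(list(coefficients = W, centers = centers, eigenvalues = vals,
                 center = mu, scale = sg, grand_mean_z = grand,
                 levels = levels(f), projection = proj, stages = f),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %d variables, %d axes, classes: %s\n",
              nrow(x$coefficients), ncol(x$coefficients),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Project an observation onto the discriminant axes
#'
#' Applies the model's standardisation and coefficient matrix; scores are
#' centred so the training grand mean maps to the origin.
#'
#' @param model a `discriminant_model`.
#' @param x named numeric vector (keyed by the model variables) or a matrix
#'   with those column names.
#' @return numeric matrix of scores (rows x axes).
#' @export
discriminant_project <- function(model, x) {
  vars <- rownames(model$coefficients)
  X <- if (is.null(dim(x))) matrix(x[vars], 1, dimnames = list(NULL, vars))
    else as.matrix(x)[, vars, drop = FALSE]
  if (any(is.na(X))) stopf("missing variables: %s",
                           paste(vars[!vars %in% names(x)], collapse = ", "))
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  sweep(Z %*% model$coefficients, 2,
        as.vector(model$grand_mean_z %*% model$coefficients))
}

#' Classify germination stage by nearest class centre
#'
#' Euclidean nearest centre in discriminant-score space; exact ties break
#' to the first class in early < mesophytic < late order.
#'
#' @param model a `discriminant_model`.
#' @param x observation(s) as in [discriminant_project()].
#' @return character vector of class labels.
#' @export
classify_stage <- function(model, x) {
  sc <- discriminant_project(model, x)
  apply(sc, 1, function(row) {
    d2 <- colSums((t(model$centers) - row)^2)
    model$levels[which.min(d2)]
  })
}

#' Germination report: confusion matrix of the fitted discriminant
#'
#' Classifies the training observations (cultivar means) by nearest centre
#' and tabulates actual vs predicted stage.
#'
#' @param model a `discriminant_model`.
#' @param X the matrix the model was fit on (defaults to reprojecting the
#'   stored training projection).
#' @return list with `confusion` (3x3), `projection` (scores per cultivar)
#'   and `centers`.
#' @export
germination_report <- function(model, X = NULL) {
  if (is.null(X)) {
    sc <- model$projection
    pred <- apply(sc, 1, function(row) {
      d2 <- colSums((t(model$centers) - row)^2)
      model$levels[which.min(d2)]
    })
  } else {
    sc <- discriminant_project(model, X)
    pred <- classify_stage(model, X)
  }
  actual <- as.character(model$stages)
  cm <- base::table(actual = factor(actual, model$levels),
                    predicted = factor(pred, model$levels))
  list(confusion = cm, projection = sc, centers = model$centers)
}

#' Evaluate the published discriminant on an observation
#'
#' Applies the fixed printed coefficients verbatim (no standardisation:
#' the coefficients are taken as given) and classifies by nearest printed
#' class centre.
#'
#' @param x named numeric 15-vector keyed by the canonical variable names
#'   (see [printed_germination_model()]).
#' @return list with `Y1`, `Y2` and `stage`.
#' @export
apply_printed_model <- function(x) {
  vars <- GERMINATION_VARIABLES
  if (!all(vars %in% names(x)))
    stopf("missing variables: %s",
          paste(setdiff(vars, names(x)), collapse = ", "))
  v <- as.numeric(x[vars])
  sc <- as.vector(v %*% PRINTED_GERMINATION_COEF)
  d2 <- colSums((t(PRINTED_GERMINATION_CENTERS) - sc)^2)
  list(Y1 = sc[1], Y2 = sc[2],
       stage = rownames(PRINTED_GERMINATION_CENTERS)[which.min(d2)])
}
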