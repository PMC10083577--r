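#' Assemble a genomic-prediction training set from program history
#'
#' Training records are the phenotyped progeny of the three completed cohorts
#' preceding the prediction generation (T-3, T-4 and T-5), matching the lag
#' with which DH lines are produced, genotyped and phenotyped. `mode`
#' restricts the component: `"elite-specific"` uses E progeny,
#' `"bridging-specific"` uses DE (bridging) progeny, `"joint"` pools both.
#'
#' @param history a `gsb_history` from the scheme engine.
#' @param mode `"elite-specific"`, `"bridging-specific"` or `"joint"`.
#' @param current_generation generation whose candidates will be predicted.
#' @return list with `genotypes` (dosages at the GS marker panel),
#'   `phenotypes` and `ids`.
#' @export
assemble_training_set <- function(history, mode = c("elite-specific",
                                                    "bridging-specific",
                                                    "joint"),
                                  current_generation) {
  mode <- match.arg(mode)
  gens <- current_generation - (3:5)
  comp <- switch(mode,
                 "elite-specific" = "elite",
                 "bridging-specific" = "bridging",
                 "joint" = c("elite", "bridging"))
  ids <- integer(0); y <- numeric(0); pops <- list()
  for (g in gens) {
    key <- as.character(g)
    pop <- history$pops[[key]]
    if (is.null(pop)) stop("no cohort recorded for generation ", g)
    keep <- pop$component %in% comp
    if (!any(keep)) next
    sub <- pop_subset(pop, which(keep))
    pops[[length(pops) + 1L]] <- sub
    ids <- c(ids, sub$id)
    y <- c(y, history$phenos[[key]][keep])
  }
  if ("bridging" %in% comp) {
    # bridging/joint calibration needs three DE cohorts to have been
    # produced, and at least one of them inside the T-3..T-5 window
    n_exist <- sum(vapply(history$pops, function(p) {
      any(p$component == "bridging")
    }, logical(1)))
    n_window <- sum(vapply(gens, function(g) {
      pop <- history$pops[[as.character(g)]]
      !is.null(pop) && any(pop$component == "bridging")
    }, logical(1)))
    if (n_exist < 3 || n_window < 1) {
      stop("bridging cohorts insufficient for mode '", mode,
           "' at generation ", current_generation,
           "; fall back to the elite-specific model")
    }
  }
  geno <- do.call(rbind, lapply(pops, function(p) {
    dosages(p, history$arch$neutral_indices)
  }))
  list(genotypes = geno, phenotypes = unname(y), ids = ids)
}

#' Fit GBLUP with a fixed error variance and backsolve marker effects
#'
#' The "direct" GBLUP fit: marker dosages are centred at training means,
#' the genomic relationship matrix is VanRaden-scaled `G = W W' / c` with
#' `c = 2 * sum(p (1 - p))` at training allele frequencies, and the shrinkage
#' parameter is fixed at `lambda = (1 - h2_model) / h2_model` instead of
#' being re-estimated by REML. Individual solutions are
#' `u = G (G + lambda I)^{-1} (y - ybar)` and marker effects are recovered by
#' backsolving, `beta = W' (G + lambda I)^{-1} (y - ybar) / c`, which is
#' identical to ridge regression on centred markers with penalty
#' `c * lambda`. The function solves in whichever of marker or individual
#' space is smaller; the two routes are algebraically identical.
#'
#' @param genotypes numeric matrix of training dosages in {0, 2}
#'   (records x markers of the GS panel).
#' @param phenotypes numeric vector of training phenotypes.
#' @param h2_model model heritability fixing the error variance
#'   (default 0.7).
#' @param ids optional training ids stored in the model.
#' @param mode training-set label stored in the model.
#' @return an object of class `gsb_gsmodel`: fields `beta` (backsolved
#'   marker effects), `intercept` (training phenotype mean), `center`
#'   (training mean dosages), `lambda`, `c_scale`, `training_ids`, `mode`.
#' @export
fit_gblup_direct <- function(genotypes, phenotypes, h2_model = 0.7,
                             ids = NULL, mode = "elite-specific") {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(n >= 2, length(phenotypes) == n)
  if (!(h2_model > 0 && h2_model <= 1)) stop("h2_model must be in (0, 1]")
  lambda <- (1 - h2_model) / h2_model
  center <- colMeans(genotypes)
  p <- center / 2
  c_scale <- 2 * sum(p * (1 - p))
  if (c_scale <= 0) stop("all training markers are fixed; cannot scale G")
  if (lambda == 0) {
    # unshrunk solve is only defined when the system is non-singular
    if (n > m || qr(genotypes)$rank < min(n, m)) {
      stop("lambda = 0 with a singular system; use h2_model < 1")
    }
  }
  W <- sweep(genotypes, 2, center)
  ybar <- mean(phenotypes)
  ystar <- phenotypes - ybar
  if (m <= n) {
    beta <- solve(crossprod(W) + diag(c_scale * lambda, m), crossprod(W, ystar))
  } else {
    beta <- crossprod(W, solve(tcrossprod(W) + diag(c_scale * lambda, n), ystar))
  }
  model <- list(
    beta = as.vector(beta), intercept = ybar, center = center,
    lambda = lambda, c_scale = c_scale, h2_model = h2_model,
    training_ids = ids, mode = mode, n_training = n
  )
  class(model) <- "gsb_gsmodel"
  model
}

#' @export
print.gsb_gsmodel <- function(x, ...) {
  cat(sprintf("<gsb_gsmodel> %s | %d training records, %d markers, lambda %.3g\n",
              x$mode, x$n_training, length(x$beta), x$lambda))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' `GEBV_i = intercept + sum_m beta_m * (dosage_im - training mean dosage_m)`,
#' using the centring stored in the model.
#'
#' @param model a `gsb_gsmodel`.
#' @param genotypes dosage matrix at the model's marker panel, or a
#'   `gsb_pop` together with `markers` giving the panel's column indices.
#' @param markers marker column indices when `genotypes` is a `gsb_pop`.
#' @return numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, genotypes, markers = NULL) {
  if (inherits(genotypes, "gsb_pop")) {
    genotypes <- dosages(genotypes, markers)
  }
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(model$beta)) {
    stop("genotype matrix does not match the model's marker panel")
  }
  as.vector(sweep(genotypes, 2, model$center) %*% model$beta) + model$intercept
}

#' Dump a fitted GS model to CSV
#'
#' @param model a `gsb_gsmodel`.
#' @param file CSV path; the first row stores intercept/lambda metadata as
#'   comment lines.
#' @return `file` invisibly.
#' @export
write_gsmodel <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# intercept=%.10g lambda=%.10g c_scale=%.10g mode=%s",
                     model$intercept, model$lambda, model$c_scale, model$mode),
             con)
  utils::write.csv(
    data.frame(marker = seq_along(model$beta), beta = model$beta,
               center = model$center),
    con, row.names = FALSE
  )
  invisible(file)
}
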