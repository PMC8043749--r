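#' Two-pass stepwise covariate selection with sex interactions
#'
#' Selects environmental covariates for a phenotype by greedy stepwise linear
#' model search. Pass one runs over the candidate main effects. Pass two
#' takes the pass-one model and searches over interactions between `sex` and
#' each selected term. Both forward and backward searches are run and the
#' function reports whether the two directions selected the same terms.
#' Continuous covariates are standardized before selection so criterion
#' values are comparable across terms.
#'
#' @param y numeric phenotype vector.
#' @param covariates data frame of candidate covariates (factors for
#'   categorical variables); must contain `sex` for the interaction pass
#'   unless `sex_var = NULL`.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param direction `"both"` (default), `"forward"`, or `"backward"` —
#'   the direction whose result is reported; the agreement check always runs
#'   forward and backward.
#' @param sex_var name of the sex column, or `NULL` to skip pass two.
#' @return An object of class `covariate_model`: list with `terms` (selected
#'   term labels, both passes), `coefficients` (estimate, SE, t, p for the
#'   final model), `criterion`, `criterion_value`, `directions_agree`, and
#'   the final `model`.
#' @export
stepwise_select <- function(y, covariates, criterion = c("aic", "bic"),
                            direction = c("both", "forward", "backward"),
                            sex_var = "sex") {
  criterion <- match.arg(criterion)
  direction <- match.arg(direction)
  dat <- as.data.frame(covariates)
  .assert(length(y) == nrow(dat), "y and covariates must have equal length")
  .assert(nrow(dat) > ncol(dat) + 2, "need n > number of candidates + 2")
  # standardize continuous candidates; leave factors/characters alone
  for (nm in names(dat)) {
    if (is.numeric(dat[[nm]]) && stats::sd(dat[[nm]]) > 0)
      dat[[nm]] <- as.numeric(scale(dat[[nm]]))
    if (is.character(dat[[nm]]) || is.logical(dat[[nm]]))
      dat[[nm]] <- factor(dat[[nm]])
  }
  # drop rank-deficient candidates up front (aliased in the full fit)
  full_fml <- stats::reformulate(names(dat), response = "y")
  dat$y <- y
  full_fit <- stats::lm(full_fml, data = dat, x = TRUE)
  asn <- attr(full_fit$x, "assign")
  tl <- attr(stats::terms(full_fit), "term.labels")
  alias_pos <- which(is.na(stats::coef(full_fit)))
  bad <- setdiff(unique(tl[asn[alias_pos]]), c("y", sex_var))
  if (length(bad)) {
    warning("dropping rank-deficient candidate term(s): ",
            paste(bad, collapse = ", "))
    dat <- dat[, setdiff(names(dat), bad), drop = FALSE]
  }
  cand <- setdiff(names(dat), "y")
  kpen <- if (criterion == "aic") 2 else log(nrow(dat))

  run_pass1 <- function(dir) {
    scope <- list(lower = y ~ 1, upper = stats::reformulate(cand, response = "y"))
    start <- if (dir == "forward") stats::lm(y ~ 1, data = dat)
             else stats::lm(scope$upper, data = dat)
    stats::step(start, scope = scope, direction = dir, k = kpen, trace = 0)
  }
  fits <- list(forward = run_pass1("forward"), backward = run_pass1("backward"))
  term_set <- function(fit) sort(attr(stats::terms(fit), "term.labels"))
  agree <- identical(term_set(fits$forward), term_set(fits$backward))
  pick <- if (direction == "backward") "backward" else "forward"
  fit1 <- fits[[pick]]
  pass1_terms <- term_set(fit1)

  # pass two: sex x (selected main effects)
  fit2 <- fit1
  if (!is.null(sex_var) && sex_var %in% names(dat)) {
    inter <- setdiff(pass1_terms, sex_var)
    if (length(inter)) {
      base_terms <- unique(c(pass1_terms, sex_var))
      upper <- stats::reformulate(
        c(base_terms, paste(sex_var, inter, sep = ":")), response = "y")
      start <- stats::lm(stats::reformulate(base_terms, response = "y"), data = dat)
      fit2 <- stats::step(start, scope = list(lower = stats::reformulate(
        base_terms, response = "y"), upper = upper),
        direction = "both", k = kpen, trace = 0)
      # keep sex only if pass one chose it or an interaction survived
      t2 <- attr(stats::terms(fit2), "term.labels")
      if (!(sex_var %in% pass1_terms) && !any(grepl(":", t2, fixed = TRUE))) {
        fit2 <- stats::lm(stats::reformulate(
          if (length(pass1_terms)) pass1_terms else "1", response = "y"),
          data = dat)
      }
    }
  }
  sm <- stats::summary.lm(fit2)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4], row.names = NULL)
  structure(list(
    terms = attr(stats::terms(fit2), "term.labels"),
    pass1_terms = pass1_terms,
    coefficients = coefs,
    criterion = criterion,
    criterion_value = stats::AIC(fit2, k = kpen),
    directions_agree = agree,
    model = fit2), class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("<covariate_model> criterion:", toupper(x$criterion),
      sprintf("(%.2f)", x$criterion_value), "\n")
  cat("selected terms:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
      "\n")
  cat("forward/backward agree:", x$directions_agree, "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
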