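#' @include AllClasses.R
NULL

#' Circadian time of acquisition
#'
#' Signed same-calendar-day difference, in decimal hours, from the
#' self-reported usual awakening time to the mid-scan time. No 24-hour
#' wrapping is applied: a negative value means the scan midpoint preceded
#' the usual awakening time on the clock, which is meaningful (acquisition
#' earlier than usual awakening).
#'
#' @param usualAwakening,midScan clock times as "HH:MM" strings (vectorized)
#' @return numeric hours in (-24, 24)
#' @examples
#' circadianTime("07:04", "12:04")  # 5.0
#' circadianTime("22:00", "08:42")  # -13.3
#' @export
circadianTime <- function(usualAwakening, midScan) {
  parseClock <- function(x) {
    m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
    bad <- vapply(m, length, 0L) != 3L
    if (any(bad))
      stop(sprintf("parse error: malformed clock time '%s'",
                   x[bad][1]))
    h <- vapply(m, function(p) as.numeric(p[2]), 0)
    mi <- vapply(m, function(p) as.numeric(p[3]), 0)
    if (any(h > 23) || any(mi > 59))
      stop("parse error: clock time out of range")
    h + mi / 60
  }
  parseClock(midScan) - parseClock(usualAwakening)
}

#' Pearson correlation with two-sided p-value
#'
#' Pairwise deletion of missing values; p from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length
#' @return list with r, p, n
#' @export
pearsonTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

# 0/1 coding for the sex column: female = 0, male = 1. Accepts 0/1
# numerics, logicals, or character/factor with levels female/male (or F/M).
codeSex <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric sex column must be 0/1")
    return(as.numeric(x))
  }
  v <- tolower(as.character(x))
  out <- ifelse(v %in% c("female", "f"), 0,
                ifelse(v %in% c("male", "m"), 1, NA_real_))
  if (anyNA(out)) stop("sex column must be female/male (or F/M, 0/1)")
  out
}

zscore <- function(x, centre = NULL) {
  s <- sd(x)
  if (s == 0) stop("zero variance in a model column")
  if (is.null(centre)) centre <- mean(x)
  (x - centre) / s
}

#' Standardized-coefficient linear model
#'
#' Ordinary least squares on a z-scored outcome and z-scored continuous
#' predictors, so each coefficient is a standardized beta (and equals the
#' Pearson r in a single-continuous-predictor model). A column named
#' \code{sex} is coded 0 (female) / 1 (male) and left unscaled, so its
#' coefficient reads as a group offset in outcome standard deviations.
#' Interaction columns are products of the already-transformed main-effect
#' columns and are then themselves z-scored. Variables listed in
#' \code{recentre} are shifted to the given origin but scaled by their
#' sample standard deviation (not mean-centred), which matters only for
#' interactions involving them.
#'
#' @param outcome outcome column name
#' @param predictors character vector of predictor column names
#' @param data data.frame; complete cases over all referenced columns are
#'   used
#' @param interactions list of length-2 character vectors naming predictor
#'   pairs
#' @param recentre named list, variable -> origin (e.g.
#'   \code{list(sleep_duration = 8)} for effects relative to 8 h of sleep
#'   per night)
#' @return list with \code{terms} (data.frame: term, beta, se, t, p),
#'   \code{n}, \code{r_squared} and \code{descriptor}
#' @export
standardizedLM <- function(outcome, predictors, data, interactions = NULL,
                           recentre = NULL) {
  vars <- unique(c(outcome, predictors, unlist(interactions)))
  stopifnot(all(vars %in% names(data)))
  cc <- complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  if (nrow(d) < length(predictors) + 2L)
    stop("too few complete cases for the requested model")
  transform1 <- function(nm) {
    if (nm == "sex") codeSex(d[[nm]])
    else zscore(as.numeric(d[[nm]]),
                centre = if (!is.null(recentre[[nm]])) recentre[[nm]])
  }
  X <- vapply(predictors, transform1, numeric(nrow(d)))
  cols <- predictors
  for (ia in interactions) {
    prod <- transform1(ia[1]) * transform1(ia[2])
    X <- cbind(X, zscore(prod))
    cols <- c(cols, paste(ia[1], ia[2], sep = ":"))
  }
  colnames(X) <- cols
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- cols[setdiff(seq_len(ncol(X) + 1L),
                            qrX$pivot[seq_len(qrX$rank)]) - 1L]
    stop(sprintf("singular design: collinear column(s) %s",
                 paste(aliased, collapse = ", ")))
  }
  y <- zscore(as.numeric(d[[outcome]]))
  fit <- lm(y ~ X)
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = cols,
                      beta = unname(sm[-1, 1]),
                      se = unname(sm[-1, 2]),
                      t = unname(sm[-1, 3]),
                      p = unname(sm[-1, 4]))
  list(terms = terms, n = nrow(d), r_squared = summary(fit)$r.squared,
       descriptor = sprintf("%s ~ %s", outcome, paste(cols, collapse = " + ")))
}

#' Two-sided pooled-variance Student's t-test
#'
#' t is computed as mean(first group) - mean(second group) over the pooled
#' standard error; df = n1 + n2 - 2. Groups follow the sorted order of the
#' grouping vector's unique values (FALSE before TRUE, 0 before 1).
#'
#' @param values numeric vector
#' @param group two-level vector (logical, 0/1, or two-level factor)
#' @return list with t, df, p, means (named by group level), n
#' @export
twoGroupT <- function(values, group) {
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop("grouping error: need exactly two non-empty groups")
  g1 <- values[group == lev[1]]; g2 <- values[group == lev[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("grouping error: each group needs at least 2 observations")
  tt <- t.test(g1, g2, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       means = setNames(c(mean(g1), mean(g2)), as.character(lev)),
       n = c(length(g1), length(g2)))
}

#' Bonferroni family-wise correction
#'
#' p_FWER = min(1, m * p), elementwise. m defaults to the number of tests
#' but may be larger (e.g. fixed at 34 for the regional screens regardless
#' of how many regions survived).
#'
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @param m number of comparisons (>= length(pvals))
#' @return corrected p-values
#' @export
bonferroniCorrect <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("validation error: p-values must lie in [0, 1]")
  if (m < length(pvals)) stop("m must be >= length(pvals)")
  pmin(1, m * pvals)
}

#' Regional screen across atlas regions with Bonferroni control
#'
#' For each region column, correlates the regional measure with a covariate
#' — by Pearson correlation when no adjustment covariates are given, or by
#' a standardized-coefficient linear model with the adjustment covariates
#' otherwise (the covariate's own beta and p are reported). P-values are
#' Bonferroni-corrected with m = \code{m} (default 34, the Desikan-Killiany
#' region count).
#'
#' @param table cohort data.frame
#' @param regionColumns character vector of regional outcome column names
#' @param covariate predictor of interest (column name)
#' @param adjust optional character vector of adjustment covariates
#' @param m Bonferroni family size (default 34)
#' @return data.frame: region, estimate, p, p_fwer, n
#' @export
regionalScreen <- function(table, regionColumns, covariate, adjust = NULL,
                           m = 34) {
  missing <- setdiff(regionColumns, names(table))
  if (length(missing))
    stop(sprintf("validation error: missing region column(s) %s",
                 paste(missing, collapse = ", ")))
  rows <- lapply(regionColumns, function(rc) {
    if (is.null(adjust)) {
      pt <- pearsonTest(table[[covariate]], table[[rc]])
      data.frame(region = rc, estimate = pt$r, p = pt$p, n = pt$n)
    } else {
      fit <- standardizedLM(rc, c(covariate, adjust), table)
      i <- match(covariate, fit$terms$term)
      data.frame(region = rc, estimate = fit$terms$beta[i],
                 p = fit$terms$p[i], n = fit$n)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fwer <- bonferroniCorrect(out$p, m = m)
  out
}

#' Read / write a cohort table (TSV, header, '.' decimal, empty = missing)
#'
#' @param path TSV path
#' @param table data.frame to write
#' @return data.frame (read) or the path, invisibly (write)
#' @export
readCohortTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE)
}

#' @rdname readCohortTable
#' @export
writeCohortTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run a set of model descriptors against a cohort table
#'
#' Descriptors may come from a YAML file with a top-level \code{models}
#' list; each entry has \code{name}, \code{outcome}, \code{predictors},
#' optional \code{interactions} (list of pairs) and \code{recentre}
#' (variable: origin).
#'
#' @param table cohort data.frame
#' @param models list of descriptor lists, or a YAML path
#' @return named list of [standardizedLM()] results
#' @export
runCohortModels <- function(table, models) {
  if (is.character(models))
    models <- yaml::read_yaml(models)$models
  out <- lapply(models, function(mdl) {
    standardizedLM(mdl$outcome, unlist(mdl$predictors), table,
                   interactions = mdl$interactions,
                   recentre = mdl$recentre)
  })
  names(out) <- vapply(models, function(mdl) mdl$name %||% mdl$outcome, "")
  out
}
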