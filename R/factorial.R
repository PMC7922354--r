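#' Melt benchmark results into a factor table
#'
#' Converts the long-format results (one row per model and validation type,
#' 25 metric columns) into the observation-level table the factorial ANOVA
#' consumes: one row per (record, performance parameter) with the factors
#' PP (performance parameter), ML (algorithm), NS (dataset size) and SR
#' (split ratio) attached.
#'
#' @param x a \linkS4class{BenchmarkResults} (normalize first with
#'   [normalizeEuclidean()]) or its results data.frame.
#' @param validation `"CV"`, `"test"`, or `"both"` (default).
#' @return data.frame with columns `value`, `PP`, `ML`, `NS`, `SR`,
#'   `Split`, and the repetition indices; `records x 25` rows.
#' @export
meltResults <- function(x, validation = c("both", "CV", "test")) {
    validation <- match.arg(validation)
    df <- if (is(x, "BenchmarkResults")) resultsTable(x) else as.data.frame(x)
    missing <- setdiff(metricNames(), colnames(df))
    if (length(missing))
        stop("metric column(s) missing from results: ",
             paste(missing, collapse = ", "))
    if (validation != "both")
        df <- df[df$Split == validation, , drop = FALSE]
    if (!nrow(df)) stop("no records selected")
    idCols <- c("ML", "SR", "NS", "balance_rep", "sample_rep", "split_rep",
                "Split")
    idCols <- intersect(idCols, colnames(df))
    out <- do.call(rbind, lapply(metricNames(), function(pp) {
        cbind(df[idCols], PP = pp, value = df[[pp]])
    }))
    out$PP <- factor(out$PP, levels = metricNames())
    out$ML <- factor(out$ML)
    out$NS <- factor(out$NS, levels = unique(df$NS))
    out$SR <- factor(out$SR)
    rownames(out) <- NULL
    out
}

termTable <- function(fit, type = "III") {
    a <- car::Anova(fit, type = type, singular.ok = TRUE)
    tab <- as.data.frame(a)
    data.frame(term = rownames(tab),
               sumsq = tab[["Sum Sq"]],
               df = tab[["Df"]],
               F = tab[["F value"]],
               p = tab[["Pr(>F)"]],
               row.names = NULL)
}

#' Fixed-effects factorial ANOVA of normalized performance
#'
#' Fits a fixed-effects linear model with the requested main factors and
#' two-way interactions to the melted factor table and returns Type III
#' tests (robust to the mild imbalance that failed cells introduce; sum
#' contrasts are applied internally).  The full four-way factorial over
#' 25 x 5 x 4 x 4 levels is impractical and not what the study design
#' needs, so interactions are configurable and default to the three
#' reported ones.
#'
#' @param table a factor table from [meltResults()].
#' @param factors main-effect factors (default `c("PP","ML","NS","SR")`);
#'   each must be present with at least 2 levels.
#' @param interactions list of 2-character vectors; defaults to
#'   `PP:NS`, `NS:SR`, `ML:NS` when all members are included in `factors`.
#' @return List of class contents: `terms` (data.frame with term, sumsq,
#'   df, F, p), `fit` (the `lm` object), and `degenerate` (TRUE when the
#'   response has zero variance, in which case `terms` is empty).
#' @export
factorialAnova <- function(table,
                           factors = c("PP", "ML", "NS", "SR"),
                           interactions = NULL) {
    stopifnot(all(factors %in% colnames(table)), "value" %in% colnames(table))
    for (f in factors) {
        table[[f]] <- droplevels(factor(table[[f]]))
        if (nlevels(table[[f]]) < 2L)
            stop("factor '", f, "' has fewer than 2 levels")
    }
    if (is.null(interactions)) {
        candidates <- list(c("PP", "NS"), c("NS", "SR"), c("ML", "NS"))
        interactions <- Filter(function(p) all(p %in% factors), candidates)
    }
    if (stats::var(table$value) == 0) {
        warning("response is constant; ANOVA is degenerate")
        return(list(terms = data.frame(term = character(), sumsq = numeric(),
                                       df = numeric(), F = numeric(),
                                       p = numeric()),
                    fit = NULL, degenerate = TRUE))
    }
    cells <- interaction(table[factors], drop = FALSE)
    if (any(table(droplevels(cells)) < 1L) ||
        nlevels(droplevels(cells)) < nlevels(cells))
        warning("unbalanced design: empty factor cell(s) present")
    rhs <- c(factors, vapply(interactions,
                             function(p) paste(p, collapse = ":"),
                             character(1)))
    form <- stats::as.formula(paste("value ~", paste(rhs, collapse = " + ")))
    contr <- lapply(factors, function(f) "contr.sum")
    names(contr) <- factors
    fit <- stats::lm(form, data = table, contrasts = contr)
    list(terms = termTable(fit), fit = fit, degenerate = FALSE)
}

#' Tukey HSD post hoc comparisons for one factor
#'
#' All pairwise comparisons of the levels of `factor`, with family-wise
#' adjusted p-values from Tukey's honest significant difference test on a
#' one-factor ANOVA of the (melted, normalized) values.
#'
#' @param table a factor table from [meltResults()] (or any data.frame with
#'   a `value` column), or a numeric vector paired with `groups`.
#' @param factor name of the factor column to compare.
#' @return List with `pMatrix` (symmetric levels x levels matrix of
#'   adjusted p-values, unit diagonal), `comparisons` (the underlying
#'   `TukeyHSD` data.frame), and `fit`.
#' @export
tukeyHsd <- function(table, factor = "SR") {
    stopifnot(factor %in% colnames(table), "value" %in% colnames(table))
    g <- droplevels(base::factor(table[[factor]]))
    if (nlevels(g) < 2L) stop("factor '", factor, "' has fewer than 2 levels")
    dat <- data.frame(value = table$value, g = g)
    fit <- stats::aov(value ~ g, data = dat)
    tk <- stats::TukeyHSD(fit)$g
    lev <- levels(g)
    pm <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lev, lev))
    for (cmp in rownames(tk)) {
        pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
        pm[pair[1], pair[2]] <- pm[pair[2], pair[1]] <- tk[cmp, "p adj"]
    }
    list(pMatrix = pm, comparisons = as.data.frame(tk), fit = fit)
}

#' Interaction (cell) means with 95% confidence intervals
#'
#' Cell means of the melted value over one or two factors, with standard
#' errors and t-based 95% confidence intervals on each cell's own degrees
#' of freedom.  For the (ML, NS) pair the cell mean is the bubble value of
#' the algorithm-by-size summary plots; for (PP, NS) it is the per-metric
#' size profile.
#'
#' @param table a factor table from [meltResults()].
#' @param factors character vector of one or two factor column names.
#' @param level confidence level (default 0.95).
#' @return data.frame with the factor columns, `n`, `mean`, `se`, `lower`,
#'   `upper`.  Empty cells are absent from the output.
#' @export
interactionMeans <- function(table, factors = c("ML", "NS"), level = 0.95) {
    stopifnot(all(factors %in% colnames(table)), "value" %in% colnames(table))
    grp <- lapply(table[factors], function(f) droplevels(base::factor(f)))
    agg <- stats::aggregate(table$value, by = grp, FUN = function(v) {
        c(n = length(v), mean = mean(v), sd = stats::sd(v))
    })
    stats <- as.data.frame(agg$x)
    out <- cbind(agg[factors], stats)
    out$se <- out$sd / sqrt(out$n)
    tq <- ifelse(out$n > 1, stats::qt(1 - (1 - level) / 2, pmax(out$n - 1, 1)),
                 NA_real_)
    out$lower <- out$mean - tq * out$se
    out$upper <- out$mean + tq * out$se
    out$sd <- NULL
    out[do.call(order, out[factors]), , drop = FALSE]
}

#' One-way ANOVA of cross-validated SRD values
#'
#' Evaluates whether the column systems (in the headline use: the four
#' train/test split ratios) differ in their fold-level SRD% values from
#' [srdCrossValidate()].
#'
#' @param cvValues folds x systems matrix as returned by
#'   [srdCrossValidate()], or a long data.frame with `value` and `group`
#'   columns.
#' @return List with `terms` (term, sumsq, df, F, p), `fit`, and
#'   `degenerate`.
#' @export
onewayAnova <- function(cvValues) {
    if (is.matrix(cvValues)) {
        long <- data.frame(
            value = as.vector(cvValues),
            group = factor(rep(colnames(cvValues), each = nrow(cvValues))))
    } else {
        long <- data.frame(value = cvValues$value,
                           group = factor(cvValues$group))
    }
    if (nlevels(long$group) < 2L) stop("at least 2 groups required")
    if (stats::var(long$value) == 0) {
        warning("response is constant; ANOVA is degenerate")
        return(list(terms = data.frame(term = character(), sumsq = numeric(),
                                       df = numeric(), F = numeric(),
                                       p = numeric()),
                    fit = NULL, degenerate = TRUE))
    }
    fit <- stats::lm(value ~ group, data = long,
                     contrasts = list(group = "contr.sum"))
    list(terms = termTable(fit), fit = fit, degenerate = FALSE)
}
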