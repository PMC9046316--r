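# Inferential layer: two-way fixed-effects species x hemisphere ANOVA and
# group mean +/- SEM tables. Hemispheres enter as independent observations
# (so a 24 + 6 subject cohort gives the 2 x 2 design its df_den = n - 4).

#' Two-way species-by-hemisphere ANOVA
#'
#' Fixed-effects decomposition of one measurement per hemisphere into
#' species, hemisphere, and interaction effects. Balanced designs use the
#' classical (Type I, order-independent) sums of squares; unbalanced
#' designs (e.g. 24 humans vs 6 macaques) use Type II.
#'
#' @param values numeric measurements, one per observation.
#' @param species factor/character with levels human/macaque (any 2 levels).
#' @param hemisphere factor/character (any 2 levels).
#' @return object of class `anova_result`: data.frame `effects` (rows
#'   species, hemisphere, interaction; columns F, df_num, df_den, p), plus
#'   `grand_n`, `design_balanced`, `ss_type`.
#' @export
two_way_anova <- function(values, species, hemisphere) {
  species <- factor(species); hemisphere <- factor(hemisphere)
  stopifnot(length(values) == length(species),
            length(values) == length(hemisphere))
  cells <- table(species, hemisphere)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: species=", rownames(cells)[bad[1]],
         ", hemisphere=", colnames(cells)[bad[2]])
  }
  if (any(cells < 2))
    stop("need at least 2 observations per design cell")
  n <- length(values)
  balanced <- length(unique(as.vector(cells))) == 1L
  if (stats::sd(values) == 0) {   # constant data: the decomposition is 0
    effects <- data.frame(effect = c("species", "hemisphere", "interaction"),
                          F = 0, df_num = 1L, df_den = n - 4L, p = 1)
    return(structure(list(effects = effects, grand_n = n,
                          design_balanced = balanced,
                          ss_type = if (balanced) "I" else "II"),
                     class = "anova_result"))
  }
  df <- data.frame(y = values, sp = species, hm = hemisphere)
  fit <- stats::lm(y ~ sp * hm, data = df)
  if (balanced) {
    tab <- stats::anova(fit)
    eff <- tab[c("sp", "hm", "sp:hm"), ]
    Fv <- eff[["F value"]]; pv <- eff[["Pr(>F)"]]
    df_num <- eff[["Df"]]
    ss_type <- "I"
  } else {
    tab <- car::Anova(fit, type = 2)
    eff <- tab[c("sp", "hm", "sp:hm"), ]
    Fv <- eff[["F value"]]; pv <- eff[["Pr(>F)"]]
    df_num <- eff[["Df"]]
    ss_type <- "II"
  }
  effects <- data.frame(effect = c("species", "hemisphere", "interaction"),
                        F = Fv, df_num = df_num, df_den = n - 4L, p = pv)
  # all-equal data: lm reports NaN F; the decomposition is exactly zero
  effects$F[is.na(effects$F) & stats::sd(values) == 0] <- 0
  effects$p[is.na(effects$p) & stats::sd(values) == 0] <- 1
  structure(list(effects = effects, grand_n = n,
                 design_balanced = balanced, ss_type = ss_type),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (species x hemisphere), n = %d, %s, Type %s SS\n",
              x$grand_n, if (x$design_balanced) "balanced" else "unbalanced",
              x$ss_type))
  print(transform(x$effects, F = signif(F, 6), p = signif(p, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Group mean and SEM table
#'
#' @param summaries data.frame of per-hemisphere sulcal summaries (rows from
#'   [summarize_sulcus()]).
#' @param measure column to aggregate, e.g. `"mean_ecc"` or `"pct_of_v1"`.
#' @return data.frame with one row per species x sulcus: `mean`, `sem`
#'   (NA when n = 1), `n`.
#' @export
group_table <- function(summaries, measure) {
  stopifnot(measure %in% names(summaries), nrow(summaries) > 0)
  agg <- function(sub) {
    v <- sub[[measure]]
    v <- v[is.finite(v)]
    data.frame(mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n = length(v))
  }
  parts <- split(summaries, list(summaries$species, summaries$sulcus),
                 drop = TRUE)
  out <- do.call(rbind, lapply(names(parts), function(nm) {
    key <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(data.frame(species = key[1], sulcus = key[2]), agg(parts[[nm]]))
  }))
  rownames(out) <- NULL
  out[order(out$sulcus, out$species), ]
}
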