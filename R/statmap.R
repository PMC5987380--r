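# Per-percentile three-way factorial ANOVA mapping: 7 effects (3 main,
# 3 two-way, 1 three-way), model R^2, residual diagnostics, banded
# significance colours and group mean / 95% CI summaries.

statmap_effects <- c("genotype", "sex", "age",
                     "genotype:sex", "genotype:age", "sex:age",
                     "genotype:sex:age")

as_factorial_table <- function(table) {
  for (f in c("genotype", "sex", "age")) {
    if (is.null(table[[f]])) stop("missing factor column: ", f)
    table[[f]] <- factor(table[[f]])
  }
  stopifnot(nlevels(table$genotype) == 2, nlevels(table$sex) == 2,
            nlevels(table$age) == 3)
  table
}

#' Three-way factorial ANOVA for one response
#'
#' Full-factorial linear model genotype x sex x age with sum-to-zero
#' contrasts and Type III sums of squares (for the balanced designs
#' generated here Type I and Type III agree, which the test suite checks).
#' Age is a categorical factor.
#'
#' @param table data.frame with columns `genotype` (2 levels), `sex` (2),
#'   `age` (3) and the response
#' @param response name of the response column
#' @return list: `p` (named, the 7 effects), `r_squared`, `fit` (the lm),
#'   `degenerate` (TRUE when the response is constant: p undefined,
#'   R^2 = 0)
#' @export
fit_factorial_anova <- function(table, response) {
  table <- as_factorial_table(table)
  cells <- base::table(interaction(table$genotype, table$sex, table$age))
  if (any(cells == 0)) {
    stop("empty factorial cell: ", names(cells)[cells == 0][1])
  }
  if (any(cells < 2)) {
    stop("cells with fewer than 2 replicates: ",
         paste(names(cells)[cells < 2], collapse = ", "))
  }
  y <- table[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  if (var(y) < .Machine$double.eps) {
    return(list(p = setNames(rep(NA_real_, 7), statmap_effects),
                r_squared = 0, fit = NULL, degenerate = TRUE))
  }
  dat <- table
  dat$.y <- y
  fit <- lm(.y ~ genotype * sex * age, data = dat,
            contrasts = list(genotype = "contr.sum", sex = "contr.sum",
                             age = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  p <- a3[statmap_effects, "Pr(>F)"]
  names(p) <- statmap_effects
  list(p = p, r_squared = summary(fit)$r.squared, fit = fit,
       degenerate = FALSE)
}

#' Residual diagnostics for a factorial fit
#'
#' Shapiro-Wilk normality on the residuals and Bartlett homogeneity across
#' the 12 factorial cells. Failures are flagged (the analysis proceeds;
#' the screen-then-proceed usage).
#'
#' @param fit_result result of [fit_factorial_anova()]
#' @return list: `shapiro_p`, `bartlett_p`, `normality_flag`,
#'   `homogeneity_flag` (TRUE = check failed at 0.05)
#' @export
residual_checks <- function(fit_result) {
  fit <- fit_result$fit
  if (is.null(fit)) stop("degenerate fit has no residuals to check")
  r <- residuals(fit)
  mf <- fit$model
  cell <- interaction(mf$genotype, mf$sex, mf$age, drop = TRUE)
  sw <- shapiro.test(r)
  bt <- bartlett.test(r, cell)
  list(shapiro_p = sw$p.value,
       bartlett_p = bt$p.value,
       normality_flag = sw$p.value < 0.05,
       homogeneity_flag = bt$p.value < 0.05)
}

#' Significance colour band for a p-value
#'
#' The exact half-open binning of the published colour rule: red
#' `p < 0.001`, yellow `0.001 <= p < 0.01`, green `0.01 <= p < 0.05`,
#' blue `p >= 0.05`.
#'
#' @param p numeric vector of p-values
#' @return factor with levels red, yellow, green, blue (NA preserved)
#' @export
significance_bands <- function(p) {
  bands <- c("red", "yellow", "green", "blue")
  idx <- findInterval(p, c(0.001, 0.01, 0.05)) + 1L
  factor(bands[idx], levels = bands)
}

#' Per-percentile factorial significance map
#'
#' Fits the three-way factorial ANOVA at every percentile of bone length
#' for each requested response, yielding p-values, R^2 and colour bands
#' per (percent, effect). No multiple-testing adjustment is applied by
#' default (interpretation rests on wide contiguous regions);
#' Benjamini-Hochberg across percentiles per effect via `fdr = TRUE`.
#'
#' @param profiles long data.frame: one row per (animal, percent) with
#'   covariate columns genotype/sex/age and the response columns
#' @param responses character vector of response column names
#' @param fdr apply BH adjustment across percentiles within each effect
#' @return data.frame of class `statmap_result`: response, percent,
#'   effect, p, band, r_squared
#' @export
heatmap_statmap <- function(profiles, responses, fdr = FALSE) {
  stopifnot(all(responses %in% names(profiles)))
  percents <- sort(unique(profiles$percent))
  grid_ok <- tapply(profiles$percent, profiles$animal, function(z) {
    identical(sort(unique(z)), percents)
  })
  if (!all(unlist(grid_ok))) {
    stop("animals do not share a common percentile grid")
  }
  out <- list()
  for (resp in responses) {
    for (pc in percents) {
      sub <- profiles[profiles$percent == pc, ]
      ft <- fit_factorial_anova(sub, resp)
      out[[length(out) + 1L]] <- data.frame(
        response = resp, percent = pc,
        effect = statmap_effects,
        p = unname(ft$p),
        r_squared = ft$r_squared,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (fdr) {
    for (resp in responses) {
      for (ef in statmap_effects) {
        sel <- res$response == resp & res$effect == ef
        res$p[sel] <- p.adjust(res$p[sel], method = "BH")
      }
    }
  }
  res$band <- significance_bands(res$p)
  class(res) <- c("statmap_result", class(res))
  res
}

#' Render a significance heatmap
#'
#' Deterministic layout: effect rows (main effects, two-way, three-way)
#' against percent of bone length, tiles filled with the fixed band
#' colours.
#'
#' @param statmap a [heatmap_statmap()] result
#' @param response which response to draw (default: first present)
#' @return a ggplot object
#' @export
plot_statmap <- function(statmap, response = NULL) {
  response <- response %||% statmap$response[1]
  d <- statmap[statmap$response == response, ]
  d$effect <- factor(d$effect, levels = rev(statmap_effects))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percent, y = .data$effect,
                                  fill = .data$band)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(red = "#d7191c",
                                          yellow = "#ffd700",
                                          green = "#1a9641",
                                          blue = "#2c7bb6"),
                               drop = FALSE, name = "p band") +
    ggplot2::labs(x = "% of bone length (proximal → distal)", y = NULL,
                  title = paste0(response, ": factorial significance map")) +
    ggplot2::theme_minimal()
}

#' Group means with 95% confidence intervals
#'
#' t-based intervals with n - 1 degrees of freedom per factorial cell.
#' Cells of one animal get an undefined (NA) interval and are flagged.
#'
#' @param table data.frame with genotype/sex/age and the response
#' @param response response column name
#' @return data.frame: one row per cell with n, mean, ci_half_width,
#'   flagged
#' @export
group_summary <- function(table, response) {
  table <- as_factorial_table(table)
  agg <- aggregate(table[[response]],
                   by = list(genotype = table$genotype, sex = table$sex,
                             age = table$age),
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = sd(v)))
  x <- as.data.frame(agg$x)
  out <- data.frame(agg[, c("genotype", "sex", "age")],
                    n = x$n, mean = x$mean)
  out$ci_half_width <- ifelse(out$n > 1,
                              qt(0.975, out$n - 1) * x$sd / sqrt(out$n),
                              NA_real_)
  out$ci_half_width[out$n > 1 & x$sd == 0] <- 0
  out$flagged <- out$n < 2
  out
}
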