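#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak procedure: with raw p-values sorted ascending,
#' \code{adj[i] = 1 - (1 - p[i])^(m - i + 1)} enforced monotone
#' non-decreasing and capped at 1. Uniformly no smaller than the raw
#' p-values.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
holmSidakAdjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, 1 - (1 - ps)^(m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Group comparisons for charging measurements
#'
#' Implements the two designs used for charged-fraction comparisons:
#' a paired two-group Student's t test, or a one-way ANOVA followed by
#' pairwise comparisons (pooled-variance t tests) with Holm-Sidak
#' step-down adjustment.
#'
#' For the degenerate paired case where all within-pair differences are
#' equal (zero variance), the t statistic is undefined: when the common
#' difference is 0 the report gives statistic 0 and p 1; otherwise the
#' difference is deterministic and p is reported as the smallest positive
#' double with a \code{zero_variance} note.
#'
#' @param values data.frame with columns \code{group}, \code{replicate},
#'   \code{value}.
#' @param design \code{"paired_two_group"} or \code{"multi_group"}.
#' @return data.frame: comparison, statistic, p_value, p_adjusted, note.
#'   For \code{multi_group} the first row is the ANOVA F test and the
#'   remaining rows the adjusted pairwise comparisons.
#' @export
compareGroups <- function(values, design = c("paired_two_group", "multi_group")) {
  design <- match.arg(design)
  stopifnot(all(c("group", "replicate", "value") %in% names(values)))
  sizes <- table(values$group)
  if (any(sizes < 2))
    stop("insufficient replication: every group needs >= 2 replicates (",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  groups <- names(sizes)

  if (design == "paired_two_group") {
    if (length(groups) != 2L)
      stop("paired design requires exactly two groups")
    if (length(unique(sizes)) != 1L)
      stop("paired design requires equal replicate counts")
    a <- values[values$group == groups[1], ]
    b <- values[values$group == groups[2], ]
    b <- b[match(a$replicate, b$replicate), ]
    if (anyNA(b$value)) stop("replicates do not pair across the two groups")
    d <- a$value - b$value
    cmp <- paste(groups[1], "vs", groups[2])
    if (sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(comparison = cmp, statistic = 0, p_value = 1,
                          p_adjusted = 1, note = "zero_variance",
                          stringsAsFactors = FALSE))
      return(data.frame(comparison = cmp, statistic = Inf * sign(mean(d)),
                        p_value = .Machine$double.xmin,
                        p_adjusted = .Machine$double.xmin,
                        note = "zero_variance", stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a$value, b$value, paired = TRUE)
    return(data.frame(comparison = cmp,
                      statistic = unname(tt$statistic),
                      p_value = tt$p.value, p_adjusted = tt$p.value,
                      note = "paired_t", stringsAsFactors = FALSE))
  }

  fit <- aov(value ~ factor(group), data = values)
  an <- summary(fit)[[1]]
  pairs <- utils::combn(groups, 2)
  pt <- stats::pairwise.t.test(values$value, values$group,
                               p.adjust.method = "none", pool.sd = TRUE)
  rawp <- apply(pairs, 2, function(g) {
    p <- pt$p.value[g[2], g[1]]
    if (is.na(p)) p <- pt$p.value[g[1], g[2]]
    p
  })
  adj <- holmSidakAdjust(rawp)
  rbind(
    data.frame(comparison = "one_way_anova",
               statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
               p_adjusted = an[["Pr(>F)"]][1], note = "anova_F",
               stringsAsFactors = FALSE),
    data.frame(comparison = apply(pairs, 2, paste, collapse = " vs "),
               statistic = NA_real_, p_value = rawp, p_adjusted = adj,
               note = "holm_sidak", stringsAsFactors = FALSE))
}
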