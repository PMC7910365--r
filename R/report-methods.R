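#' @export
print.auth_report <- function(x, ...) {
  cat("<auth_report> peptide authentication summary\n")
  cnt <- x$counts
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  %-12s %4d observations, %4d distinct peptides\n",
                cnt$class[i], cnt$n_observations[i], cnt$n_peptides[i]))
  }
  pooled <- x$deamidation[x$deamidation$sample_id == "(pooled)", , drop = FALSE]
  if (nrow(pooled) > 0L) {
    cat("  pooled deamidation (point %, 95% CI):\n")
    for (i in seq_len(nrow(pooled))) {
      cat(sprintf(
        "    %-12s %s  %5.1f%%  [%.1f, %.1f]\n",
        pooled$class[i], pooled$residue_type[i], pooled$point_pct[i],
        pooled$ci95_low_pct[i], pooled$ci95_high_pct[i]
      ))
    }
  }
  cl <- x$cleavage[x$cleavage$sample_id == "(pooled)", , drop = FALSE]
  for (i in seq_len(nrow(cl))) {
    cat(sprintf(
      "  non-enzymatic cleavage, %-12s %d / %d (%.1f%%)\n",
      cl$class[i], cl$numerator[i], cl$denominator[i], 100 * cl$fraction[i]
    ))
  }
  fr <- x$fold_ratios[x$fold_ratios$sample_id == "(pooled)", , drop = FALSE]
  for (i in seq_len(nrow(fr))) {
    lab <- if (is.na(fr$fold[i])) "undefined" else sprintf("%.1f-fold", fr$fold[i])
    cat(sprintf("  food/contaminant deamidation ratio (%s): %s\n",
                fr$residue_type[i], lab))
  }
  invisible(x)
}

#' Tidy an authentication report
#'
#' @param x An `auth_report`.
#' @param ... Unused.
#' @return The per-sample, per-class deamidation estimate table.
#' @method tidy auth_report
#' @export
tidy.auth_report <- function(x, ...) {
  x$deamidation
}

#' One-row report summary
#'
#' @param x An `auth_report`.
#' @param ... Unused.
#' @return A one-row tibble with observation/peptide counts, pooled
#'   non-enzymatic fractions and pooled fold ratios.
#' @method glance auth_report
#' @export
glance.auth_report <- function(x, ...) {
  cnt_of <- function(cls, col) {
    v <- x$counts[[col]][x$counts$class == cls]
    if (length(v) == 0L) 0L else v
  }
  pooled_frac <- function(cls) {
    v <- x$cleavage$fraction[x$cleavage$sample_id == "(pooled)" &
                               x$cleavage$class == cls]
    if (length(v) == 0L) NA_real_ else v
  }
  pooled_fold <- function(res) {
    v <- x$fold_ratios$fold[x$fold_ratios$sample_id == "(pooled)" &
                              x$fold_ratios$residue_type == res]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble::tibble(
    n_food_peptides = cnt_of("food", "n_peptides"),
    n_contaminant_peptides = cnt_of("contaminant", "n_peptides"),
    n_ambiguous = cnt_of("ambiguous", "n_observations"),
    nonenzymatic_food = pooled_frac("food"),
    nonenzymatic_contaminant = pooled_frac("contaminant"),
    fold_ratio_N = pooled_fold("N"),
    fold_ratio_Q = pooled_fold("Q"),
    n_groups_accepted = sum(x$groups$accepted, na.rm = TRUE),
    n_groups_rejected = sum(!x$groups$accepted, na.rm = TRUE)
  )
}

#' Deamidation bar chart
#'
#' Bar chart of the per-sample deamidation percentage by residue type and
#' class, with bootstrap 95% intervals, in the style of a per-sample
#' deamidation summary figure.
#'
#' @param object An `auth_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot auth_report
#' @export
autoplot.auth_report <- function(object, ...) {
  d <- object$deamidation
  d <- d[d$sample_id != "(pooled)" & !is.na(d$point_pct), , drop = FALSE]
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$sample_id, y = .data$point_pct, fill = .data$class)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci95_low_pct, ymax = .data$ci95_high_pct),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::facet_wrap(~residue_type, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "sample", y = "deamidation (%)", fill = "peptide class",
      title = "Intensity-weighted deamidation by sample and class"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.auth_report
#' @export
plot_deamidation <- function(object, ...) autoplot.auth_report(object, ...)
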