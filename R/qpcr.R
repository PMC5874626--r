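#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of Cq on log10(copies) over a dilution
#' series of standards (typically 10^1 to 10^7 copies). Reports the slope,
#' intercept (Cq at one copy), r2, amplification efficiency
#' 10^(-1/slope) - 1 and the dynamic range.
#'
#' @param copies standard template amounts (copies per reaction), >= 3
#'   points spanning at least two decades.
#' @param cq measured quantification cycles.
#' @param gene optional gene label carried through.
#' @return Object of class `"qpcr_curve"`.
#' @export
fit_standard_curve <- function(copies, cq, gene = NA_character_) {
  if (length(copies) != length(cq)) stop_input("copies and cq differ in length")
  if (length(copies) < 3) stop_input("at least 3 dilution points are required")
  if (any(copies <= 0)) stop_input("copies must be > 0")
  lg <- log10(copies)
  if (max(lg) - min(lg) < 2)
    stop_input("standards must span at least two decades")
  fit <- stats::lm(cq ~ lg)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop_input("positive slope: standards appear inverted")
  tss <- sum((cq - mean(cq))^2)
  structure(list(
    gene = gene,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss
                else NA_real_,
    efficiency = 10^(-1 / slope) - 1,
    dynamic_range = range(copies),
    cq_range = range(unname(stats::fitted(fit))),
    n = length(copies)
  ), class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve%s: Cq = %.3f %+.4f log10(copies)\n",
              if (!is.na(x$gene)) paste0(" [", x$gene, "]") else "",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.3f, r2 = %.4f, range %.0g-%.0g copies\n",
              x$efficiency, x$r_squared,
              x$dynamic_range[1], x$dynamic_range[2]))
  invisible(x)
}

#' Absolute quantification of gene copies per gram dry soil
#'
#' Converts duplicate Cq measurements to copies per reaction via the
#' standard curve (duplicates averaged on the Cq scale), then through the
#' extraction chain to copies per gram of dry soil:
#' copies_per_rxn x (elution_uL / template_uL) / (wet_mass_g x
#' (1 - water_content)). Results below the lowest standard are censored
#' ("below quantification"); Cq outside the curve's dynamic range or
#' duplicates differing by more than 0.5 Cq are flagged.
#'
#' @param cq numeric vector of replicate Cq values (usually 2).
#' @param curve a [fit_standard_curve()] result.
#' @param template_uL template volume per reaction.
#' @param elution_uL DNA-extract elution volume.
#' @param wet_mass_g wet soil mass extracted.
#' @param water_content gravimetric water-content fraction in [0, 1).
#' @return List with `copies_per_g_dry`, `copies_per_rxn`, `mean_cq`,
#'   `cq_spread`, `censored` and a character vector of `flags`.
#' @export
quantify <- function(cq, curve, template_uL, elution_uL, wet_mass_g,
                     water_content) {
  stopifnot(inherits(curve, "qpcr_curve"))
  if (any(cq <= 0)) stop_input("Cq must be > 0")
  check_number(template_uL, "template_uL", 0, strict_lower = TRUE)
  check_number(elution_uL, "elution_uL", 0, strict_lower = TRUE)
  check_number(water_content, "water_content", 0, 1, strict_upper = TRUE)
  if (wet_mass_g <= 0 || wet_mass_g * (1 - water_content) <= 0)
    stop_input("dry soil mass must be > 0")
  flags <- character(0)
  spread <- if (length(cq) > 1) max(cq) - min(cq) else NA_real_
  if (!is.na(spread) && spread > 0.5) flags <- c(flags, "duplicate_spread")
  mcq <- mean(cq)
  copies_rxn <- 10^((mcq - curve$intercept) / curve$slope)
  if (copies_rxn > curve$dynamic_range[2]) flags <- c(flags, "extrapolated_high")
  censored <- copies_rxn < curve$dynamic_range[1]
  if (censored) flags <- c(flags, "below_quantification")
  per_g <- copies_rxn * (elution_uL / template_uL) /
    (wet_mass_g * (1 - water_content))
  list(copies_per_g_dry = per_g, copies_per_rxn = copies_rxn,
       mean_cq = mcq, cq_spread = spread, censored = censored,
       flags = flags)
}

#' Quantify a qPCR table against per-gene standard curves
#'
#' @param qpcr data.frame: `sample_id, gene, cq_rep1, cq_rep2, template_uL,
#'   elution_uL, wet_mass_g, water_content`.
#' @param standards data.frame: `gene, copies, cq`.
#' @return data.frame `sample_id, gene, copies_per_g_dry, censored, flags`
#'   with the fitted curves as attribute `"curves"`.
#' @export
run_qpcr <- function(qpcr, standards) {
  require_columns(qpcr, c("sample_id", "gene", "cq_rep1", "cq_rep2",
                          "template_uL", "elution_uL", "wet_mass_g",
                          "water_content"), "qpcr")
  require_columns(standards, c("gene", "copies", "cq"), "standards")
  genes <- unique(qpcr$gene)
  curves <- lapply(stats::setNames(genes, genes), function(g) {
    s <- standards[standards$gene == g, ]
    if (nrow(s) == 0) stop_input("no standards for gene '", g, "'")
    fit_standard_curve(s$copies, s$cq, gene = g)
  })
  rows <- lapply(seq_len(nrow(qpcr)), function(i) {
    r <- qpcr[i, ]
    q <- quantify(c(r$cq_rep1, r$cq_rep2), curves[[r$gene]], r$template_uL,
                  r$elution_uL, r$wet_mass_g, r$water_content)
    data.frame(sample_id = r$sample_id, gene = r$gene,
               copies_per_g_dry = q$copies_per_g_dry,
               censored = q$censored,
               flags = paste(q$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
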