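# Named parameter bundles that encode the study's printed effect sizes as
# synthetic ground truth. Only the ratios/percentages are anchored to reported
# results; absolute levels (stain colors, colony means, LDH totals, growth
# rates) are invented design values documented in the methods vignette.
.preset_table <- function() {
  list(
    `ki67-fig3c` = list(
      name = "ki67-fig3c",
      type = "ihc",
      control_fraction = 0.25,
      treated_fraction = 0.16,
      note = paste(
        "Proliferation-marker (Ki67) stained-area study:",
        "treated/control ground-truth area ratio 0.64, i.e. a 36% decrease."
      )
    ),
    `cd34-fig3d` = list(
      name = "cd34-fig3d",
      type = "ihc",
      control_fraction = 0.10,
      treated_fraction = 0.076,
      note = paste(
        "Vessel-marker (CD34) stained-area study:",
        "treated/control ground-truth area ratio 0.76, i.e. a 24% decrease."
      )
    ),
    `ldh-fig4a` = list(
      name = "ldh-fig4a",
      type = "ldh",
      total_signal = 1.8,
      # per-condition step profiles: released/total from `from_h` hours onward
      profile = tibble::tibble(
        condition = c("control", "1uM", "1uM", "7.5uM", "7.5uM"),
        from_h = c(0, 0, 3, 0, 3),
        fraction = c(0.02, 0.07, 0.15, 0.40, 0.80)
      ),
      note = paste(
        "LDH release time course: control wells leak 2% of total LDH;",
        "1 uM releases 15% and 7.5 uM 80% from 3 h onward",
        "(pre-3 h levels are design values)."
      )
    ),
    `colony-fig1b` = list(
      name = "colony-fig1b",
      type = "colony",
      doses_uM = c(0, 0.1, 1, 2.5, 5),
      means = c(30, 7.5, 3, 0, 0),
      note = paste(
        "Soft-agar colony formation: control mean 30 colonies/well (invented",
        "absolute level); 0.1 uM mean = 0.25x control (>70% inhibition);",
        "complete inhibition at >= 2.5 uM."
      )
    ),
    `tumor-fig3a` = list(
      name = "tumor-fig3a",
      type = "tumor",
      endpoint_ratio = 0.45,
      dispersion_cv = 0.6,
      v0_mm3 = 25,
      control_endpoint_mm3 = 600,
      duration_days = 47,
      aspect_ratio = 1.3,
      note = paste(
        "Xenograft growth: treated endpoint mean volume = 0.45x control",
        "(>50% inhibition) with lognormal per-mouse dispersion (CV 0.6);",
        "enrollment volume 25 mm3, 47-day course."
      )
    )
  )
}

#' Shipped synthetic-study presets
#'
#' Each preset bundles the generator parameters that reproduce one of the
#' study's quantified effect sizes with synthetic data: stained-area fractions
#' for the immunohistochemistry studies, release-fraction step profiles for
#' the LDH plate, per-dose colony means, and the tumor-growth endpoint ratio.
#'
#' @param name preset name; one of `"ki67-fig3c"`, `"cd34-fig3d"`,
#'   `"ldh-fig4a"`, `"colony-fig1b"`, `"tumor-fig3a"`.
#' @return `synth_preset()` returns a `synth_preset` object (a named parameter
#'   list); `synth_presets()` returns a tibble listing all presets.
#' @examples
#' synth_presets()
#' synth_preset("ki67-fig3c")
#' @export
synth_preset <- function(name) {
  tab <- .preset_table()
  if (inherits(name, "synth_preset")) return(name)
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab)) {
    stop_ihc(sprintf(
      "unknown preset '%s'; available: %s",
      paste(name, collapse = ","), paste(names(tab), collapse = ", ")
    ), "ihcquant_bad_input")
  }
  structure(tab[[name]], class = "synth_preset")
}

#' @rdname synth_preset
#' @export
synth_presets <- function() {
  tab <- .preset_table()
  tibble::tibble(
    name = names(tab),
    type = vapply(tab, function(p) p$type, character(1)),
    note = vapply(tab, function(p) p$note, character(1))
  )
}

#' @export
print.synth_preset <- function(x, ...) {
  cat(sprintf("<synth_preset '%s'> (%s)\n%s\n", x$name, x$type, x$note))
  invisible(x)
}
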