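#' Describe a transfection recipe
#'
#' A recipe is a table of liquid components mixed before delivery. Exactly
#' one component may be flagged as the nucleic-acid payload (the siRNA or
#' miRNA); its stock concentration and volume determine the final payload
#' concentration. For the well format the delivery volume defaults to the
#' sum of component volumes (the whole mix is added to one well); for the
#' array format it is the pooled printing-mix volume.
#'
#' @param components data frame with columns `name`, `volume_ul`,
#'   `stock_conc_um` (numeric, `NA` for non-payload components) and
#'   `payload` (logical).
#' @param format `"well"` or `"array"`.
#' @param final_delivery_volume_ul delivery volume in microlitres; defaults
#'   to the sum of component volumes.
#' @return a `transfection_recipe` object.
#' @export
transfection_recipe <- function(components, format = c("well", "array"),
                                final_delivery_volume_ul = NULL) {
  format <- match.arg(format)
  req <- c("name", "volume_ul", "stock_conc_um", "payload")
  if (!all(req %in% names(components)))
    stop_pa("components must have columns: %s", paste(req, collapse = ", "),
            class = "phenoarray_bad_arg")
  if (any(components$volume_ul <= 0))
    stop_pa("all component volumes must be positive",
            class = "phenoarray_bad_arg")
  if (sum(components$payload) > 1L)
    stop_pa("at most one component may be the payload",
            class = "phenoarray_bad_arg")
  vol <- final_delivery_volume_ul %||% sum(components$volume_ul)
  if (vol <= 0)
    stop_pa("final delivery volume must be positive",
            class = "phenoarray_bad_arg")
  structure(list(components = components, format = format,
                 final_delivery_volume_ul = vol),
            class = "transfection_recipe")
}

#' @export
print.transfection_recipe <- function(x, ...) {
  cat(sprintf("transfection_recipe (%s format, %g uL delivered)\n",
              x$format, x$final_delivery_volume_ul))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Built-in well-format siRNA recipe
#'
#' The standard forward-transfection mix for one well of a 96-well plate:
#' 5 uL of 1 uM siRNA with lipid reagent and medium, 100 uL delivered,
#' giving a 50 nM final siRNA concentration.
#' @return a `transfection_recipe`.
#' @export
recipe_well_sirna <- function() {
  transfection_recipe(data.frame(
    name = c("DMEM (reagent dilution)", "DharmaFECT 2",
             "DMEM (siRNA dilution)", "siRNA", "DMEM (complete)"),
    volume_ul = c(9.9, 0.1, 5, 5, 80),
    stock_conc_um = c(NA, NA, NA, 1, NA),
    payload = c(FALSE, FALSE, FALSE, TRUE, FALSE)), format = "well")
}

#' Built-in array-format printing mix
#'
#' The pooled reverse-transfection printing mix: 2 uL of 20 uM siRNA plus
#' lipid reagent, sucrose, water, tracer (siGLO) and gelatin, 16 uL pooled,
#' giving a 2.5 uM (2,500 nM) payload concentration in the printed mix.
#' @return a `transfection_recipe`.
#' @export
recipe_array_sirna <- function() {
  transfection_recipe(data.frame(
    name = c("lipofectamine", "siRNA", "0.3 M sucrose in OptiMEM",
             "RNase-free water", "siGLO tracer", "0.2% gelatin"),
    volume_ul = c(3, 2, 2, 2, 2, 5),
    stock_conc_um = c(NA, 20, NA, NA, NA, NA),
    payload = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    format = "array")
}

#' Final payload concentration of a recipe
#'
#' Payload amount (volume x stock concentration) divided by the final
#' delivery volume, in nanomolar.
#'
#' @param recipe a [transfection_recipe()].
#' @return concentration in nM.
#' @examples
#' final_payload_concentration(recipe_well_sirna())   # 50 nM
#' final_payload_concentration(recipe_array_sirna())  # 2500 nM
#' @export
final_payload_concentration <- function(recipe) {
  stopifnot(inherits(recipe, "transfection_recipe"))
  p <- recipe$components[recipe$components$payload, , drop = FALSE]
  if (nrow(p) != 1L || is.na(p$stock_conc_um))
    stop_pa("recipe has no payload component with a stock concentration",
            class = "phenoarray_no_payload")
  # uL * uM / uL = uM; express in nM
  1000 * p$volume_ul * p$stock_conc_um / recipe$final_delivery_volume_ul
}

#' Read / write a recipe as CSV
#'
#' The CSV carries the component table plus `format` and
#' `final_delivery_volume_ul` columns (repeated on every row).
#' @param recipe a `transfection_recipe`.
#' @param path file path.
#' @return `read_recipe_csv` returns a `transfection_recipe`.
#' @export
write_recipe_csv <- function(recipe, path) {
  df <- recipe$components
  df$format <- recipe$format
  df$final_delivery_volume_ul <- recipe$final_delivery_volume_ul
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recipe_csv
#' @export
read_recipe_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  transfection_recipe(
    df[c("name", "volume_ul", "stock_conc_um", "payload")],
    format = df$format[1L],
    final_delivery_volume_ul = df$final_delivery_volume_ul[1L])
}

#' Build a Ct table for relative quantification
#'
#' Each row carries the qPCR cycle-threshold (Ct) of the target gene and of
#' a reference gene (for example GAPDH, a proxy for cell number) in one
#' sample; one sample is the calibrator everything is expressed against.
#'
#' @param rows data frame with columns `sample`, `target_ct`,
#'   `reference_ct`.
#' @param calibrator_sample name of the calibrator sample (must be a row).
#' @return a `ct_table` object.
#' @export
ct_table <- function(rows, calibrator_sample) {
  req <- c("sample", "target_ct", "reference_ct")
  if (!all(req %in% names(rows)))
    stop_pa("rows must have columns: %s", paste(req, collapse = ", "),
            class = "phenoarray_bad_arg")
  if (anyDuplicated(rows$sample))
    stop_pa("duplicate sample names in Ct table",
            class = "phenoarray_duplicate_sample")
  cts <- c(rows$target_ct, rows$reference_ct)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop_pa("Ct values must be finite and positive",
            class = "phenoarray_bad_arg")
  if (!calibrator_sample %in% rows$sample)
    stop_pa("calibrator sample '%s' not found", calibrator_sample,
            class = "phenoarray_bad_arg")
  structure(list(rows = rows, calibrator_sample = calibrator_sample),
            class = "ct_table")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-sample fold change relative to the calibrator:
#' `fold = efficiency^-(ddCt)` with `dCt = target_ct - reference_ct` and
#' `ddCt = dCt_sample - dCt_calibrator`. With the default amplification
#' efficiency of 2 (perfect doubling per cycle) this is the standard
#' `2^-ddCt` scheme; the calibrator maps to exactly 1.
#'
#' @param ct a [ct_table()].
#' @param efficiency amplification efficiency per cycle (default 2.0).
#' @return data frame with `sample`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change` and `percent_of_calibrator`.
#' @examples
#' tab <- ct_table(data.frame(
#'   sample = c("control", "siRNA"),
#'   target_ct = c(20, 23.5), reference_ct = c(18, 19.2)),
#'   calibrator_sample = "control")
#' relative_expression(tab)
#' @export
relative_expression <- function(ct, efficiency = 2.0) {
  stopifnot(inherits(ct, "ct_table"))
  if (efficiency <= 1)
    stop_pa("amplification efficiency must exceed 1",
            class = "phenoarray_bad_arg")
  rows <- ct$rows
  dct <- rows$target_ct - rows$reference_ct
  dct_cal <- dct[rows$sample == ct$calibrator_sample]
  ddct <- dct - dct_cal
  fold <- efficiency^(-ddct)
  data.frame(sample = rows$sample, delta_ct = dct, delta_delta_ct = ddct,
             fold_change = fold, percent_of_calibrator = 100 * fold,
             stringsAsFactors = FALSE)
}

#' Read a Ct table from CSV
#'
#' Expects columns `sample`, `target_ct`, `reference_ct`; the calibrator is
#' either passed explicitly or marked with a logical `calibrator` column.
#' @param path CSV path.
#' @param calibrator_sample calibrator name; default: the row with
#'   `calibrator == TRUE`.
#' @return a `ct_table`.
#' @export
read_ct_csv <- function(path, calibrator_sample = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(calibrator_sample)) {
    if (!"calibrator" %in% names(df))
      stop_pa("no calibrator column and no calibrator_sample given",
              class = "phenoarray_bad_arg")
    calibrator_sample <- df$sample[which(as.logical(df$calibrator))[1L]]
  }
  ct_table(df[c("sample", "target_ct", "reference_ct")], calibrator_sample)
}
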