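#' Haemolysis assay data
#'
#' Spectrophotometric absorbances (540 nm, free haemoglobin) for
#' nanoparticle-incubated red-blood-cell samples bracketed by a negative
#' control (buffer, intact cells) and a positive control (fully lysed
#' cells). A valid assay requires the positive control to absorb strictly
#' more than the negative one, otherwise the normalizing denominator
#' vanishes.
#'
#' @param samples Data frame with columns `label`, `concentration_uM` and
#'   `absorbance` (one row per replicate).
#' @param abs_negative,abs_positive Control absorbances (replicate vectors
#'   allowed; their means define the controls).
#' @return An object of class `hemolysis_assay`.
#' @export
hemolysis_assay <- function(samples, abs_negative, abs_positive) {
  if (any(c(samples$absorbance, abs_negative, abs_positive) < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  neg <- mean(abs_negative); pos <- mean(abs_positive)
  if (pos <= neg)
    stop("assay invalid: positive control must absorb more than negative",
         call. = FALSE)
  structure(list(samples = samples, abs_negative = neg, abs_positive = pos),
            class = "hemolysis_assay")
}

#' Haemolysis fraction per sample
#'
#' Normalizes each replicate's absorbance between the controls,
#' \deqn{h = \frac{A_{sample} - A_{neg}}{A_{pos} - A_{neg}},}
#' then summarizes replicates per sample as mean and standard deviation.
#' The statistic is invariant to adding a constant to all three
#' absorbances and to scaling all three by a positive factor. Fractions
#' below zero (sample clearer than the negative control, a routine
#' blank-variation artefact) are reported as computed and flagged, never
#' clipped.
#'
#' @param assay A [hemolysis_assay()].
#' @return Data frame: label, concentration_uM, fraction, percent, sd,
#'   n_replicates, below_zero.
#' @export
hemolysis_fraction <- function(assay) {
  stopifnot(inherits(assay, "hemolysis_assay"))
  den <- assay$abs_positive - assay$abs_negative
  s <- assay$samples
  s$fraction <- (s$absorbance - assay$abs_negative) / den
  split_by <- interaction(s$label, s$concentration_uM, drop = TRUE)
  rows <- lapply(split(s, split_by), function(g) {
    data.frame(label = g$label[1],
               concentration_uM = g$concentration_uM[1],
               fraction = mean(g$fraction),
               percent = 100 * mean(g$fraction),
               sd = if (nrow(g) > 1) stats::sd(g$fraction) else 0,
               n_replicates = nrow(g),
               below_zero = mean(g$fraction) < 0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$concentration_uM), ]
  rownames(out) <- NULL
  out
}

#' Read a haemolysis assay from CSV
#'
#' Expected columns: `label`, `concentration_uM`, `replicate`,
#' `absorbance`, `role` (one of sample/negative/positive). Control rows
#' define the assay's negative/positive absorbances.
#'
#' @param path CSV file path.
#' @return A [hemolysis_assay()].
#' @export
read_hemolysis_assay <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "concentration_uM", "replicate", "absorbance", "role")
  if (!all(need %in% names(d)))
    stop("assay CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(d$role), c("sample", "negative", "positive"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  hemolysis_assay(samples = d[d$role == "sample", ],
                  abs_negative = d$absorbance[d$role == "negative"],
                  abs_positive = d$absorbance[d$role == "positive"])
}
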