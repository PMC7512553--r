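## Delta-delta-Ct relative quantification against a calibrator small RNA
## (U6), the reference-unit-mass arithmetic used for RT-qPCR validation of
## a differential small RNA.

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = target_ct - calibrator_ct`; then
#' `ddCt = mean(dCt(test)) - mean(dCt(reference))` (replicates averaged on
#' the dCt scale) and the fold ratio is `efficiency^(-ddCt)` with the
#' classic amplification efficiency of 2.  A fold below 1 means lower
#' expression in the test group than in the reference; above 1, the
#' multiple by which the test group exceeds it.
#'
#' @param test,reference data.frames with numeric columns `target_ct` and
#'   `calibrator_ct` (one row per replicate); Ct values must lie in
#'   (0, 45) and the calibrator must be present for every sample.
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return list with `ddct` and `fold`.
#' @examples
#' test <- data.frame(target_ct = c(20, 20.2), calibrator_ct = c(15, 15.1))
#' ref  <- data.frame(target_ct = c(22, 22.1), calibrator_ct = c(15, 15.2))
#' relativeExpression(test, ref)$fold
#' @export
relativeExpression <- function(test, reference, efficiency = 2) {
    dct <- function(df, label) {
        need <- c("target_ct", "calibrator_ct")
        if (!all(need %in% names(df)))
            stop(label, " measurements need columns: ",
                 paste(need, collapse = ", "))
        if (nrow(df) < 1L) stop(label, " group has no measurements")
        if (anyNA(df$calibrator_ct))
            stop("missing calibrator Ct in ", label, " group")
        ct <- c(df$target_ct, df$calibrator_ct)
        if (anyNA(ct) || any(ct <= 0 | ct >= 45))
            stop("Ct values must lie in (0, 45) in ", label, " group")
        mean(df$target_ct - df$calibrator_ct)
    }
    ddct <- dct(test, "test") - dct(reference, "reference")
    list(ddct = ddct, fold = efficiency^(-ddct))
}
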