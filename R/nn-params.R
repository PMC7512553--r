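## Nearest-neighbor thermodynamic parameters for RNA/RNA Watson-Crick
## helices: enthalpy (kcal/mol) and entropy (cal/(mol K)) per stacked base
## pair, plus duplex initiation and the terminal A-U penalty.  Values are
## the standard Xia et al. (1998) / Turner-2004 RNA set.  Stacks are keyed
## by the two consecutive pairs read 5'->3' on the top strand: "AU/UG"
## means top strand 5'-A U-3' paired to bottom strand 3'-U G-5' (the bottom
## key is also written 5'->3' of the top, i.e. position-aligned).

.NN_XIA1998 <- data.frame(
    top    = c("AA", "AU", "UA", "CU", "CA", "GU", "GA", "CG", "GG", "GC"),
    bottom = c("UU", "UA", "AU", "GA", "GU", "CA", "CU", "GC", "CC", "CG"),
    dH = c(-6.82, -9.38, -7.69, -10.48, -10.44, -11.40, -12.44, -10.64,
           -13.39, -14.88),
    dS = c(-19.0, -26.7, -20.5, -27.1, -26.9, -29.5, -32.5, -26.7,
           -32.7, -36.9),
    stringsAsFactors = FALSE)

.NN_INIT <- c(dH = 3.61, dS = -1.5)       # duplex initiation
.NN_TERM_AU <- c(dH = 3.72, dS = 10.5)    # per terminal A-U pair

#' Nearest-neighbor parameter table
#'
#' Returns the shipped stacked-pair parameter set used by
#' [duplexEnergy()]: one row per Watson-Crick stack with enthalpy `dH`
#' (kcal/mol) and entropy `dS` (cal/(mol K)), and attributes `initiation`
#' and `terminal_AU` carrying the duplex-initiation and terminal-A-U
#' corrections.  The free energy of a stack at temperature T (Kelvin) is
#' `dH - T * dS / 1000`.
#'
#' @param set parameter-set identifier; currently only `"xia1998"`.
#' @return data.frame with columns `top`, `bottom`, `dH`, `dS`.
#' @examples
#' head(nnParameters())
#' @export
nnParameters <- function(set = "xia1998") {
    if (!identical(set, "xia1998"))
        stop("unknown nearest-neighbor parameter set: ", set)
    out <- .NN_XIA1998
    attr(out, "initiation") <- .NN_INIT
    attr(out, "terminal_AU") <- .NN_TERM_AU
    out
}
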