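#' Roadmap-style 15 chromatin state labels
#'
#' @return Character vector of the 15 core chromatin-state mnemonics.
#' @export
roadmap_states <- function() {
  c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG",
    "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk",
    "12_EnhBiv", "13_ReprPC", "14_ReprPCWk", "15_Quies")
}

#' Simulate a chromatin-state annotation track
#'
#' Tiles a genomic region with contiguous non-overlapping half-open
#' intervals of random length and assigns each a chromatin state. State
#' probabilities default to a quiescent-dominated genome; supplying
#' `state_prob` lets tests plant specific state compositions.
#'
#' @param chrom Chromosome name.
#' @param region Length-2 region bounds (0-based start, end).
#' @param mean_width Mean interval width in bp.
#' @param state_prob Optional length-15 probability vector over
#'   [roadmap_states()].
#' @param seed Integer seed.
#' @return BED-like data.frame: chrom, start, end, state.
#' @export
simulate_chromatin_states <- function(chrom = "6",
                                      region = c(29640168, 33115544),
                                      mean_width = 2000,
                                      state_prob = NULL, seed = 1L) {
  set.seed(seed)
  states <- roadmap_states()
  if (is.null(state_prob)) {
    state_prob <- c(rep(0.04, 14), 0.44)
  }
  stopifnot(length(state_prob) == length(states))
  span <- region[2] - region[1]
  widths <- pmax(200, round(stats::rexp(ceiling(2 * span / mean_width),
                                        rate = 1 / mean_width)))
  edges <- region[1] + cumsum(widths)
  edges <- c(region[1], edges[edges < region[2]], region[2])
  data.frame(chrom = chrom, start = edges[-length(edges)],
             end = edges[-1],
             state = sample(states, length(edges) - 1L, replace = TRUE,
                            prob = state_prob / sum(state_prob)),
             stringsAsFactors = FALSE)
}
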