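#' A three-step example network
#'
#' The smallest network used throughout the documentation: a substrate
#' exchange (uptake bound 10), a gene-associated transport step, and a
#' biomass sink.  Its FBA optimum is 10.
#'
#' @param uptake substrate uptake bound magnitude.
#' @return a \code{metabolic_model}.
#' @examples
#' m <- example_chain_model()
#' fba(m)$objective_value   # 10
#' @export
example_chain_model <- function(uptake = 10) {
  S <- rbind(A = c(-1, -1, 0),
             B = c(0, 1, -1))
  colnames(S) <- c("EX_a", "T1", "BIOMASS")
  metabolic_model(S, lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
                  gpr = c("", "g1", ""), objective_id = "BIOMASS",
                  id = "chain3")
}
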