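## Small atom-mapped example networks, built in code. Used throughout the
## documentation and tests: the linear chain and condensation networks have
## closed-form labeling, the branched glucose network is fully identifiable
## from tracer data (parameter-recovery experiments), and the symmetric
## loop exercises scrambling at a symmetric intermediate.

.toy <- function(name, mets, rxns, uptake, value = 100) {
  flux_model(list(
    name = name,
    metabolites = lapply(mets, function(m)
      list(id = m[[1]], atoms = m[[2]], external = isTRUE(m[[3]]))),
    reactions = rxns,
    uptake = list(reaction = uptake, value = value)))
}

.tr <- function(id, subs, prods, lb = 0, ub = 1000, weights = 1) {
  maps <- lapply(seq_along(weights), function(i)
    list(weight = weights[i],
         substrates = lapply(subs[[i]], function(e)
           list(met = e[[1]], atoms = e[[2]])),
         products = lapply(prods[[i]], function(e)
           list(met = e[[1]], atoms = e[[2]]))))
  list(id = id, lb = lb, ub = ub, mappings = maps)
}

#' Packaged toy networks
#'
#' @param name One of:
#' \describe{
#'   \item{`"chain"`}{Linear pathway A -> B -> C (2 carbons): MDVs pass
#'     through unchanged.}
#'   \item{`"condensation"`}{X (2C) + Y (2C) -> Z (4C): the product MDV is
#'     the convolution of the substrate MDVs.}
#'   \item{`"branched"`}{Glucose consumed by a glycolysis-like split into
#'     two trioses and an oxidative decarboxylating branch, with a
#'     pyruvate-carboxylation condensation re-using released CO2; fluxes
#'     are informed by pyruvate/lactate/oxaloacetate labeling.}
#'   \item{`"symmetric"`}{A 4-carbon pathway passing through a symmetric
#'     succinate-like intermediate (0.5/0.5 scrambling variants).}
#'   \item{`"cycle"`}{A TCA-like cycle: a 4-carbon acceptor condenses with a
#'     2-carbon unit, two decarboxylations return the (symmetric) 4-carbon
#'     acceptor; exercises condensation, cycling and scrambling together.}
#' }
#' @return A `flux_model`.
#' @export
toy_model <- function(name = c("chain", "condensation", "branched",
                               "symmetric", "cycle")) {
  name <- match.arg(name)
  switch(name,
    chain = .toy("chain",
      list(list("A_x", 2L, TRUE), list("A", 2L, FALSE), list("B", 2L, FALSE),
           list("C", 2L, FALSE), list("C_x", 2L, TRUE)),
      list(.tr("up", list(list(list("A_x", "ab"))), list(list(list("A", "ab")))),
           .tr("r1", list(list(list("A", "ab"))), list(list(list("B", "ab")))),
           .tr("r2", list(list(list("B", "ab"))), list(list(list("C", "ab")))),
           .tr("out", list(list(list("C", "ab"))), list(list(list("C_x", "ab"))))),
      "up"),
    condensation = .toy("condensation",
      list(list("X_x", 2L, TRUE), list("Y_x", 2L, TRUE), list("X", 2L, FALSE),
           list("Y", 2L, FALSE), list("Z", 4L, FALSE), list("Z_x", 4L, TRUE)),
      list(.tr("upx", list(list(list("X_x", "ab"))), list(list(list("X", "ab")))),
           .tr("upy", list(list(list("Y_x", "ab"))), list(list(list("Y", "ab")))),
           .tr("cond", list(list(list("X", "ab"), list("Y", "cd"))),
               list(list(list("Z", "abcd")))),
           .tr("out", list(list(list("Z", "abcd"))), list(list(list("Z_x", "abcd"))))),
      "upx"),
    branched = .toy("branched",
      list(list("GLC_x", 6L, TRUE), list("GLC", 6L, FALSE),
           list("P5", 5L, FALSE), list("TRI", 3L, FALSE), list("C2", 2L, FALSE),
           list("PYR", 3L, FALSE), list("LAC", 3L, FALSE), list("OAA", 4L, FALSE),
           list("CO2", 1L, FALSE), list("C2_x", 2L, TRUE), list("LAC_x", 3L, TRUE),
           list("PYR_x", 3L, TRUE), list("OAA_x", 4L, TRUE), list("CO2_x", 1L, TRUE)),
      list(.tr("GLCup", list(list(list("GLC_x", "abcdef"))),
               list(list(list("GLC", "abcdef"))), lb = 100, ub = 100),
           .tr("EMP", list(list(list("GLC", "abcdef"))),
               list(list(list("TRI", "cba"), list("TRI", "def"))), ub = 150),
           .tr("OXP", list(list(list("GLC", "abcdef"))),
               list(list(list("CO2", "a"), list("P5", "bcdef"))), ub = 150),
           .tr("P5X", list(list(list("P5", "abcde"))),
               list(list(list("C2", "ab"), list("TRI", "cde"))), ub = 150),
           .tr("C2out", list(list(list("C2", "ab"))),
               list(list(list("C2_x", "ab"))), ub = 150),
           .tr("PK", list(list(list("TRI", "abc"))),
               list(list(list("PYR", "abc"))), ub = 300),
           .tr("LDH", list(list(list("PYR", "abc"))),
               list(list(list("LAC", "abc"))), ub = 300),
           .tr("LACout", list(list(list("LAC", "abc"))),
               list(list(list("LAC_x", "abc"))), ub = 300),
           .tr("PC", list(list(list("PYR", "abc"), list("CO2", "d"))),
               list(list(list("OAA", "abcd"))), ub = 150),
           .tr("OAAout", list(list(list("OAA", "abcd"))),
               list(list(list("OAA_x", "abcd"))), ub = 150),
           .tr("PYRout", list(list(list("PYR", "abc"))),
               list(list(list("PYR_x", "abc"))), ub = 300),
           .tr("CO2out", list(list(list("CO2", "a"))),
               list(list(list("CO2_x", "a"))), ub = 300)),
      "GLCup"),
    symmetric = .toy("symmetric",
      list(list("A_x", 4L, TRUE), list("A", 4L, FALSE), list("S", 4L, FALSE),
           list("M", 4L, FALSE), list("M_x", 4L, TRUE)),
      list(.tr("up", list(list(list("A_x", "abcd"))), list(list(list("A", "abcd")))),
           .tr("toS", list(list(list("A", "abcd")), list(list("A", "abcd"))),
               list(list(list("S", "abcd")), list(list("S", "dcba"))),
               weights = c(0.5, 0.5)),
           .tr("toM", list(list(list("S", "abcd"))), list(list(list("M", "abcd")))),
           .tr("out", list(list(list("M", "abcd"))), list(list(list("M_x", "abcd"))))),
      "up"),
    cycle = .toy("cycle",
      list(list("AcU_x", 2L, TRUE), list("AcU", 2L, FALSE),
           list("OAA", 4L, FALSE), list("C6", 6L, FALSE), list("C5", 5L, FALSE),
           list("C4", 4L, FALSE), list("CO2", 1L, FALSE), list("CO2_x", 1L, TRUE)),
      list(.tr("up", list(list(list("AcU_x", "ab"))), list(list(list("AcU", "ab")))),
           .tr("cond", list(list(list("OAA", "abcd"), list("AcU", "ef"))),
               list(list(list("C6", "abcdef")))),
           .tr("dec1", list(list(list("C6", "abcdef"))),
               list(list(list("CO2", "a"), list("C5", "bcdef")))),
           .tr("dec2", list(list(list("C5", "abcde")), list(list("C5", "abcde"))),
               list(list(list("CO2", "a"), list("C4", "bcde")),
                    list(list("CO2", "a"), list("C4", "edcb"))),
               weights = c(0.5, 0.5)),
           .tr("back", list(list(list("C4", "abcd"))), list(list(list("OAA", "abcd")))),
           .tr("co2out", list(list(list("CO2", "a"))), list(list(list("CO2_x", "a"))))),
      "up"))
}
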