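#' Packaged toy case-study instances
#'
#' Three small, fully deterministic instances whose optimal solutions
#' reproduce the weight accounting of the two published consortium case
#' studies at desk scale. They mirror the *composition* of the reported
#' optimal designs (how many endogenous reactions, insertions and transports
#' the optimum buys, and at which weights), not the genome-scale KEGG
#' networks those designs were found in.
#'
#' \describe{
#'   \item{`antibiotics_toy`}{Two organisms, a *Streptomyces cattleya*-like
#'   producer and a *Methanosarcina barkeri*-like partner, growing on
#'   cellulose. The penicillin / cephalosporin C branch (including the
#'   three-substrate ACV synthase, a tentacular hyperarc consuming
#'   L-2-aminoadipate, L-valine and L-cysteine) must be inserted from
#'   reference organisms; 2-oxoadipate can only be made by the partner, so
#'   the optimum transports pyruvate out and 2-oxoadipate back. Solved with
#'   weights 1/100/100 the optimum costs 528 = 28 endogenous + 3 insertions
#'   + 2 transports.}
#'   \item{`pdo_toy`}{A *Klebsiella pneumoniae*-like glycerol scavenger
#'   producing 1,3-propanediol and a *Methanosarcina mazei*-like methanogen
#'   producing methane. Both targets from glycerol force one metabolite
#'   exchange (pyruvate); the optimum costs 110 = 10 endogenous + 1
#'   transition at uniform weights 1/100/100.}
#'   \item{`pdo_acetate_toy`}{Same topology plus a pyruvate-to-acetate step
#'   and an acetate uptake in the methanogen. With the transport of the
#'   organic acid acetate discounted to 50, the optimum switches to the
#'   acetate exchange and costs 61 = 11 endogenous + 1 transition at 50.}
#' }
#'
#' @param name one of `"antibiotics_toy"`, `"pdo_toy"`, `"pdo_acetate_toy"`.
#' @return A [ConsortiumInstance-class].
#' @examples
#' inst <- consortiumFixture("pdo_toy")
#' optimalWeight(solveDsh(inst))  # 110
#' @export
consortiumFixture <- function(name) {
  fixtures <- c("antibiotics_toy", "pdo_toy", "pdo_acetate_toy")
  if (length(name) != 1L || !name %in% fixtures)
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available fixtures: ", paste(fixtures, collapse = ", "),
         call. = FALSE)
  switch(name,
         antibiotics_toy = .fixtureAntibiotics(),
         pdo_toy = .fixturePdo(acetate = FALSE),
         pdo_acetate_toy = .fixturePdo(acetate = TRUE))
}

.fixtureAntibiotics <- function() {
  chain <- function(prefix, compounds) {
    n <- length(compounds) - 1L
    .reactionSet(sprintf("%s%d", prefix, seq_len(n)),
                 as.list(compounds[-length(compounds)]),
                 as.list(compounds[-1]), FALSE)
  }
  sc <- rbind(
    # upper glycolysis from cellulose down to pyruvate (8 steps)
    chain("r_gly", c("cellulose", "cellobiose", "bD_glucose", "g6p", "f6p",
                     "fbp", "gap", "pep", "pyruvate")),
    # valine biosynthesis from pyruvate (4 steps)
    chain("r_val", c("pyruvate", "acetolactate", "dihydroxy_isovalerate",
                     "oxo_isovalerate", "L_valine")),
    # cysteine branch off glyceraldehyde 3-phosphate (5 steps)
    chain("r_cys", c("gap", "pg3", "php3", "phosphoserine", "serine",
                     "L_cysteine")),
    # aminoadipate from imported 2-oxoadipate (1 step)
    .reactionSet("r_aad", list("oxoadipate"), list("aminoadipate"), FALSE))
  mb <- chain("r_tca", c("pyruvate", "malate", "oxaloacetate", "citrate",
                         "cis_aconitate", "isocitrate", "oxoglutarate",
                         "homocitrate", "homoaconitate", "homoisocitrate",
                         "oxoadipate"))
  refs <- rbind(
    # ACV synthase: the tentacular three-substrate step starting the
    # beta-lactam branch
    .reactionSet("ref_acvs", list(c("aminoadipate", "L_valine", "L_cysteine")),
                 list("acv"), FALSE),
    .reactionSet("ref_ipns", list("acv"), list("penicillin"), FALSE),
    .reactionSet("ref_ceph", list("acv"), list("cephalosporin_C"), FALSE))
  buildInstance(
    networks = list(s_cattleya = sc, m_barkeri = mb),
    sources = vertexId("cellulose", "s_cattleya"),
    targets = vertexId(c("penicillin", "cephalosporin_C"), "s_cattleya"),
    referenceReactions = refs,
    weights = WeightConfig(wWorker = 1, wOther = 100, wTransition = 100))
}

.fixturePdo <- function(acetate = FALSE) {
  chain <- function(prefix, compounds) {
    n <- length(compounds) - 1L
    .reactionSet(sprintf("%s%d", prefix, seq_len(n)),
                 as.list(compounds[-length(compounds)]),
                 as.list(compounds[-1]), FALSE)
  }
  kp <- rbind(
    # glycerol -> 3-hydroxypropanal -> 1,3-propanediol
    chain("r_pdo", c("glycerol", "hpa3", "pdo")),
    # glycerol -> pyruvate (5 steps)
    chain("r_glp", c("glycerol", "glycerone", "glycerone_p", "gap", "pep",
                     "pyruvate")))
  mm <- chain("r_mtg", c("pyruvate", "acetyl_coa", "methyl_com", "methane"))
  if (acetate) {
    kp <- rbind(kp, .reactionSet("r_poxB", list("pyruvate"), list("acetate"),
                                 FALSE))
    mm <- rbind(.reactionSet("r_ack", list("acetate"), list("acetyl_coa"),
                             FALSE), mm)
  }
  weights <- if (acetate)
    WeightConfig(wWorker = 1, wOther = 100, wTransition = 100,
                 overrides = list(transition = c(acetate = 50)))
  else WeightConfig(wWorker = 1, wOther = 100, wTransition = 100)
  buildInstance(
    networks = list(k_pneumoniae = kp, m_mazei = mm),
    sources = vertexId("glycerol", "k_pneumoniae"),
    targets = c(vertexId("pdo", "k_pneumoniae"),
                vertexId("methane", "m_mazei")),
    weights = weights)
}
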