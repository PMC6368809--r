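# Worked-example fixtures: the four case-study derivations, encoded line by
# line in the Step/Reason layout, with two documented corrections to
# apparent typesetting errors in the printed derivations (see the
# individual fixtures below and the methods vignette).

#' Worked-example derivation fixtures
#'
#' Returns the four bundled case studies in which given premises extracted
#' for an unannotated protein lead, through the specification rules and the
#' standard inference rules, to a protein-function conclusion:
#'
#' * `ex1`: given `FD(Px)`, `ST(Px)`; conclusion `F(Px)` (5-line proof via
#'   Conjunction and Conditional Proof on R1).
#' * `ex2`: given `AAS(Px)`, `AAS(Py)`; conclusions `F(Py)` and `F(Px)`
#'   (13-line proof via R2 and the two symmetric instantiations of R10).
#'   The printed derivation cites "M10" at step 12; the fixture reads it as
#'   R10 (instantiated with the protein roles swapped).
#' * `ex3`: given `ST(Px)`; conclusion `F(Px)` (5-line proof via R13 and R3
#'   with two Modus Ponens steps).
#' * `ex4`: given `NCBND(Px, Py)`, `F(Px)`; conclusion `F(Py)` (9-line
#'   proof via R12, R6, R7). The printed antecedent indices of steps 5 and
#'   6 are corrected to 3 & 4 (Law of Syllogism on the two rule instances)
#'   and 1 & 5 (Modus Ponens); formulas, rule names and the 9-line
#'   structure are unchanged.
#'
#' Here `Px`, `Py` are ground protein constants standing for the named
#' proteins the premises were extracted about.
#'
#' @return A named list (`ex1` .. `ex4`); each element is a list with
#'   `given` (list of ground formulas), `given_text`, `rule_ids` (the
#'   specification rules used), `conclusions` (character, the expected
#'   newly derived `F` atoms), `constants` (tibble `name`, `sort`) and
#'   `proof` (a `pl_proof`).
#' @examples
#' fx <- worked_example_fixtures()
#' check_proof(fx$ex1$proof, fx$ex1$given, spec_rules())$valid
#' @export
worked_example_fixtures <- function() {
  ex <- function(given_text, rule_ids, conclusions, constants, text, kind, rule, ants) {
    list(
      given = lapply(given_text, parse_formula),
      given_text = given_text,
      rule_ids = rule_ids,
      conclusions = conclusions,
      constants = constants,
      proof = proof_from_lines(text, kind, rule, ants)
    )
  }
  px <- tibble::tibble(name = "Px", sort = "protein")
  pxy <- tibble::tibble(name = c("Px", "Py"), sort = "protein")

  list(
    ex1 = ex(
      given_text = c("FD(Px)", "ST(Px)"),
      rule_ids = "R1",
      conclusions = "F(Px)",
      constants = px,
      text = c("FD(Px)", "ST(Px)", "FD(Px) & ST(Px)",
               "FD(Px) -> (ST(Px) -> F(Px))", "F(Px)"),
      kind = c("given", "given", "inference_rule", "specification_rule",
               "inference_rule"),
      rule = c("given", "given", "Conjunction", "R1", "ConditionalProof"),
      ants = list(integer(0), integer(0), c(1L, 2L), integer(0), c(3L, 4L))
    ),
    ex2 = ex(
      given_text = c("AAS(Px)", "AAS(Py)"),
      rule_ids = c("R2", "R10"),
      conclusions = c("F(Px)", "F(Py)"),
      constants = pxy,
      text = c(
        "AAS(Px)",                                        # 1 given
        "AAS(Py)",                                        # 2 given
        "AAS(Px) & AAS(Py)",                              # 3 Conjunction 1,2
        "AAS(Px) -> ST(Px)",                              # 4 R2
        "ST(Px)",                                         # 5 ModusPonens 1,4
        "(AAS(Px) & AAS(Py)) & ST(Px)",                   # 6 Conjunction 3,5
        "AAS(Px) & AAS(Py) -> (ST(Px) -> F(Py))",         # 7 R10
        "F(Py)",                                          # 8 ConditionalProof 6,7
        "AAS(Py) -> ST(Py)",                              # 9 R2
        "ST(Py)",                                         # 10 ModusPonens 2,9
        "(AAS(Px) & AAS(Py)) & ST(Py)",                   # 11 Conjunction 3,10
        # Step 12 is R10 instantiated with the protein roles swapped; the
        # printed derivation cites it as "M10".
        "AAS(Px) & AAS(Py) -> (ST(Py) -> F(Px))",         # 12 R10 (roles swapped)
        "F(Px)"                                           # 13 ConditionalProof 11,12
      ),
      kind = c("given", "given", "inference_rule", "specification_rule",
               "inference_rule", "inference_rule", "specification_rule",
               "inference_rule", "specification_rule", "inference_rule",
               "inference_rule", "specification_rule", "inference_rule"),
      rule = c("given", "given", "Conjunction", "R2", "ModusPonens",
               "Conjunction", "R10", "ConditionalProof", "R2", "ModusPonens",
               "Conjunction", "R10", "ConditionalProof"),
      ants = list(integer(0), integer(0), c(1L, 2L), integer(0), c(1L, 4L),
                  c(3L, 5L), integer(0), c(6L, 7L), integer(0), c(2L, 9L),
                  c(3L, 10L), integer(0), c(11L, 12L))
    ),
    ex3 = ex(
      given_text = "ST(Px)",
      rule_ids = c("R13", "R3"),
      conclusions = "F(Px)",
      constants = px,
      text = c("ST(Px)", "ST(Px) -> AAS(Px)", "AAS(Px)",
               "AAS(Px) -> F(Px)", "F(Px)"),
      kind = c("given", "specification_rule", "inference_rule",
               "specification_rule", "inference_rule"),
      rule = c("given", "R13", "ModusPonens", "R3", "ModusPonens"),
      ants = list(integer(0), integer(0), c(1L, 2L), integer(0), c(3L, 4L))
    ),
    ex4 = ex(
      given_text = c("NCBND(Px, Py)", "F(Px)"),
      rule_ids = c("R12", "R6", "R7"),
      conclusions = "F(Py)",
      constants = pxy,
      text = c(
        "NCBND(Px, Py)",                                  # 1 given
        "F(Px)",                                          # 2 given
        "NCBND(Px, Py) -> PPI(Px, Py)",                   # 3 R12
        "PPI(Px, Py) -> PCF(Px, Py)",                     # 4 R6
        # Steps 5 and 6: antecedent indices corrected (printed as 1 & 5 and
        # 6 & 7); formulas and rule names as printed.
        "NCBND(Px, Py) -> PCF(Px, Py)",                   # 5 LawOfSyllogism 3,4
        "PCF(Px, Py)",                                    # 6 ModusPonens 1,5
        "PCF(Px, Py) & F(Px)",                            # 7 Conjunction 2,6
        "PCF(Px, Py) -> (F(Px) -> F(Py))",                # 8 R7
        "F(Py)"                                           # 9 ConditionalProof 7,8
      ),
      kind = c("given", "given", "specification_rule", "specification_rule",
               "inference_rule", "inference_rule", "inference_rule",
               "specification_rule", "inference_rule"),
      rule = c("given", "given", "R12", "R6", "LawOfSyllogism", "ModusPonens",
               "Conjunction", "R7", "ConditionalProof"),
      ants = list(integer(0), integer(0), integer(0), integer(0), c(3L, 4L),
                  c(1L, 5L), c(2L, 6L), integer(0), c(7L, 8L))
    )
  )
}
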