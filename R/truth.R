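#' The three-ligand toy competition model
#'
#' A minimal 3-ligand x 2 Type I x 2 Type II instance of the competitive
#' equilibrium model that reproduces, by construction, the signature
#' redistribution behaviors of promiscuous receptor competition:
#' \itemize{
#' \item the pink ligand binds the black/black and white/black receptor
#'   dimers strongly but silently, and the white/white dimer weakly but
#'   with high activity -- so its signal comes from its least-favored
#'   complex;
#' \item the blue ligand mirrors pink but cannot form the white/black
#'   complex;
#' \item the gold ligand binds white/white strongly with low activity and
#'   white/black weakly without activity.
#' }
#' Consequences (each verifiable with [solve_equilibrium()]): knocking down
#' the black Type I receptor frees black Type II subunits, sequesters
#' pink's white Type I receptors into the silent white/black complex, and
#' so reduces pink's output through a receptor that was never perturbed;
#' gold outcompetes pink for white/white, so the pair signals below either
#' ligand alone (suppression); and pink+blue is saturated additive in the
#' wild type but antagonistic in the knockdown, where sequestered pink
#' limits blue.
#'
#' @return list with `params` ([model_params()]), `contexts` (named list:
#'   `wild_type`, `knockdown` with the black Type I receptor reduced
#'   20-fold), `environments` (named list of single- and paired-ligand dose
#'   vectors), and `dose` (the common dose used).
#' @export
toy_model_factory <- function() {
  tab <- data.frame(
    ligand = c("pink", "pink", "pink",
               "blue", "blue",
               "gold", "gold"),
    type1 = c("I_black", "I_white", "I_white",
              "I_black", "I_white",
              "I_white", "I_white"),
    type2 = c("II_black", "II_black", "II_white",
              "II_black", "II_white",
              "II_white", "II_black"),
    K = c(20, 20, 0.1,
          20, 0.1,
          20, 0.1),
    eps = c(0, 0, 20,
            0, 20,
            4, 0),
    stringsAsFactors = FALSE)
  params <- model_params(tab, ligands = c("pink", "blue", "gold"),
                         type1 = c("I_black", "I_white"),
                         type2 = c("II_black", "II_white"))
  contexts <- list(
    wild_type = receptor_context(c(I_black = 1, I_white = 1),
                                 c(II_black = 1, II_white = 1)),
    knockdown = receptor_context(c(I_black = 0.05, I_white = 1),
                                 c(II_black = 1, II_white = 1)))
  dose <- 10
  environments <- list(
    pink = c(pink = dose), blue = c(blue = dose), gold = c(gold = dose),
    pink_blue = c(pink = dose, blue = dose),
    pink_gold = c(pink = dose, gold = dose))
  list(params = params, contexts = contexts, environments = environments,
       dose = dose)
}

#' Packaged ground truth for the synthetic ten-ligand screen
#'
#' A 10-ligand x 2 Type I x 3 Type II parameter set, with a wild-type and a
#' Type-I-knockdown receptor context, whose noiseless screen exhibits the
#' interaction repertoire of the real panel: mostly (saturated) additive
#' pairs, antagonism by non-activating competitors, suppressive pairs
#' (L03/L04/L05 + L06: a receptor-sequestering weak ligand starves the
#' strong activators of Type I receptor), and synergistic pairs (L01/L02 +
#' L06 or L08: a silent super-binder of the I1/II1 sink pulls II1 out of
#' the pink family's I2-locking complex, redistributing I2 to the active
#' complex). Interaction magnitudes are placed well clear of the category
#' boundaries and of the replicate-noise gate, so the planted structure is
#' recoverable from realistically noisy screens.
#'
#' @return list with `params`, `contexts`, and `panel` (a [ligand_panel()]
#'   with per-ligand top doses near saturation and shallower dilution folds
#'   for the weak ligands, as in the real screen design).
#' @export
example_screen_truth <- function() {
  rows <- list(
    # L01, L02: strong activators signaling through their least-favored
    # complex (pink motif): silent sinks at I1/II1 and I2/II1, active
    # complex I2/II2
    c("L01", "I1", "II1", 8, 0), c("L01", "I2", "II1", 3, 0),
    c("L01", "I2", "II2", 0.8, 20),
    c("L02", "I1", "II1", 8, 0), c("L02", "I2", "II1", 3, 0),
    c("L02", "I2", "II2", 0.8, 20),
    # L03-L05: robust strong activators through I1/II3
    c("L03", "I1", "II3", 4, 6), c("L03", "I1", "II1", 0.05, 0),
    c("L04", "I1", "II3", 4, 6), c("L04", "I1", "II1", 0.05, 0),
    c("L05", "I1", "II3", 4, 6), c("L05", "I1", "II1", 0.05, 0),
    # L06: weak alone (its silent I1/II1 sink starves its own active
    # complex of I1); suppresses L03-L05 by the same starvation
    c("L06", "I1", "II1", 25, 0), c("L06", "I1", "II3", 2, 30),
    # L07: gold motif -- strong, low-activity binder of the pink family's
    # active complex I2/II2
    c("L07", "I2", "II2", 16, 2), c("L07", "I2", "II1", 0.01, 0),
    # L08: silent super-binder of the I1/II1 sink; pulls II1 out of the
    # pink family's I2/II1 complexes, releasing I2 -> synergy with pink
    c("L08", "I1", "II1", 30, 0.01),
    # L09: blue motif -- like L01 but cannot form the I2/II1 complex
    c("L09", "I1", "II1", 8, 0), c("L09", "I2", "II2", 0.8, 20),
    # L10: non-activator antagonist of the I1/II3 users
    c("L10", "I1", "II3", 4, 0.002))
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(ligand = r[1], type1 = r[2], type2 = r[3],
               K = as.numeric(r[4]), eps = as.numeric(r[5]),
               stringsAsFactors = FALSE)))
  ligs <- sprintf("L%02d", 1:10)
  params <- model_params(tab, ligands = ligs, type1 = c("I1", "I2"),
                         type2 = c("II1", "II2", "II3"))
  contexts <- list(
    ctx_wt = receptor_context(c(I1 = 1, I2 = 1),
                              c(II1 = 1, II2 = 1, II3 = 1)),
    ctx_kd = receptor_context(c(I1 = 0.05, I2 = 1),
                              c(II1 = 1, II2 = 1, II3 = 1)))
  weak <- ligs %in% c("L06", "L07", "L08", "L10")
  panel <- ligand_panel(ligs, top = 100, fold = ifelse(weak, 2, 3))
  list(params = params, contexts = contexts, panel = panel)
}

#' Packaged ground truth for fit-recovery experiments
#'
#' A 5-ligand x 2 Type I x 3 Type II truth (one representative per
#' equivalence-group archetype) observed in four receptor contexts
#' (wild type plus three knockdowns), used to verify that multi-start
#' fitting recovers the planted interaction structure from noiseless
#' responses.
#'
#' @return list with `params`, `contexts` (4 contexts), `receptor_expr`
#'   (raw expression lists, input for [assemble_observations()]), `panel`.
#' @export
example_fit_truth <- function() {
  rows <- list(
    # F1: pink motif -- strong activator through its least-favored complex
    c("F1", "A1", "B1", 4, 0), c("F1", "A2", "B1", 3, 0),
    c("F1", "A2", "B2", 0.8, 20),
    # F2: robust strong activator through A1/B3
    c("F2", "A1", "B3", 4, 6), c("F2", "A1", "B1", 0.05, 0),
    # F3: weak alone (silent A1/B1 sink starves its own A1/B3 active
    # complex); suppresses F2, synergizes with F1
    c("F3", "A1", "B1", 25, 0), c("F3", "A1", "B3", 1, 30),
    # F4: gold motif -- strong, low-activity binder of F1's active complex
    c("F4", "A2", "B2", 16, 2), c("F4", "A2", "B1", 0.01, 0),
    # F5: silent super-binder of the A1/B1 sink -> synergy with F1
    c("F5", "A1", "B1", 30, 0.01))
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(ligand = r[1], type1 = r[2], type2 = r[3],
               K = as.numeric(r[4]), eps = as.numeric(r[5]),
               stringsAsFactors = FALSE)))
  ligs <- paste0("F", 1:5)
  params <- model_params(tab, ligands = ligs, type1 = c("A1", "A2"),
                         type2 = c("B1", "B2", "B3"))
  receptor_expr <- list(
    fit_wt = list(A0 = c(A1 = 1, A2 = 1), B0 = c(B1 = 1, B2 = 1, B3 = 1)),
    fit_kdA1 = list(A0 = c(A1 = 0.05, A2 = 1), B0 = c(B1 = 1, B2 = 1, B3 = 1)),
    fit_kdA2 = list(A0 = c(A1 = 1, A2 = 0.15), B0 = c(B1 = 1, B2 = 1, B3 = 1)),
    fit_kdB2 = list(A0 = c(A1 = 1, A2 = 1), B0 = c(B1 = 1, B2 = 0.15, B3 = 1)))
  contexts <- lapply(receptor_expr, function(e) receptor_context(e$A0, e$B0))
  weak <- ligs %in% c("F3", "F4", "F5")
  panel <- ligand_panel(ligs, top = 100, fold = ifelse(weak, 2, 3))
  list(params = params, contexts = contexts, receptor_expr = receptor_expr,
       panel = panel)
}
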