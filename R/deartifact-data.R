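#' Recipe for the de-artifact training mixture
#'
#' Default proportions follow the published dataset: 10,000 missing-wedge
#' WBP : 7,500 missing-wedge SART : 7,500 complete WBP : 20,000
#' inpainted-then-WBP (i.e. 2/9 : 1/6 : 1/6 : 4/9 of 45,000), scaled to the
#' requested corpus size.  The complete-WBP subset exists so that
#' over-de-artifacting of already-clean inputs is prevented; the inpainted
#' subset is drawn evenly across the listed inpainting checkpoints, whose
#' varying restoration strength diversifies the artifact patterns.
#'
#' @param fractions named fractions over
#'   `c(mw_wbp, mw_sart, complete_wbp, inpainted_wbp)`; must sum to 1.
#' @param checkpoints indices (or epochs) of inpainting checkpoints for the
#'   inpainted subset.
#' @return list of class `"deartifact_recipe"`.
#' @export
deartifact_recipe <- function(fractions = c(mw_wbp = 2 / 9, mw_sart = 1 / 6,
                                            complete_wbp = 1 / 6,
                                            inpainted_wbp = 4 / 9),
                              checkpoints = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  need <- c("mw_wbp", "mw_sart", "complete_wbp", "inpainted_wbp")
  if (!setequal(names(fractions), need))
    abort("fractions must be named mw_wbp, mw_sart, complete_wbp, inpainted_wbp")
  structure(list(fractions = fractions[need], checkpoints = checkpoints),
            class = "deartifact_recipe")
}

# Largest-remainder apportionment of `total` across `fractions`, ties broken
# by position.
apportion <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assemble the de-artifact training dataset
#'
#' For each drawn phantom the input tomogram is built per its subset --
#' missing-wedge WBP, missing-wedge SART, complete WBP, or
#' checkpoint-inpainted WBP -- and the target is always the original
#' phantom.  Subset labels are retained for stratified evaluation.
#'
#' @param phantoms list of phantom matrices to draw from (with replacement
#'   when `total` exceeds the library size).
#' @param checkpoints a `wf_checkpoints` from [train_inpainting()] (used for
#'   the inpainted subset; must be nonempty).
#' @param recipe a [deartifact_recipe()].
#' @param total number of samples to produce.
#' @param seed integer seed for the draws.
#' @param grid,wedge projection geometry.
#' @param sart_cfg [iterative_config()] for the SART subset.
#' @return list of `list(input, target, subset, checkpoint)` samples.
#' @export
assemble_deartifact_dataset <- function(phantoms, checkpoints,
                                        recipe = deartifact_recipe(),
                                        total = 45, seed = 0L,
                                        grid = angle_grid(),
                                        wedge = wedge_spec(),
                                        sart_cfg = iterative_config()) {
  if (length(checkpoints$entries) == 0) abort("no inpainting checkpoints")
  sizes <- apportion(recipe$fractions, total)
  names(sizes) <- names(recipe$fractions)
  if (any(sizes == 0))
    abort("`total` too small to honor all four subsets")
  cks <- recipe$checkpoints %||% seq_along(checkpoints$entries)
  draws <- with_seed(derive_seed(seed, 7),
                     sample(seq_along(phantoms), total, replace = TRUE))
  samples <- vector("list", total)
  q <- 0
  subset_of <- rep(names(sizes), sizes)
  # even split of the inpainted subset across checkpoints
  ck_cycle <- rep(cks, length.out = sizes[["inpainted_wbp"]])
  ck_i <- 0
  for (q in seq_len(total)) {
    ph <- phantoms[[draws[q]]]
    sub <- subset_of[q]
    full <- normalize_sinogram(forward_project(ph, grid))
    masked <- apply_missing_wedge(full, wedge)
    ck_used <- NA
    input <- switch(sub,
      mw_wbp = reconstruct_wbp(masked),
      mw_sart = reconstruct_sart(masked, sart_cfg),
      complete_wbp = reconstruct_wbp(full),
      inpainted_wbp = {
        ck_i <- ck_i + 1
        ck_used <- ck_cycle[ck_i]
        gm <- checkpoint_model(checkpoints, ck_used)
        reconstruct_wbp(composite_inpaint(gm, masked))
      })
    samples[[q]] <- list(input = unclass(input), target = unclass(ph),
                         subset = sub, checkpoint = ck_used)
  }
  samples
}
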