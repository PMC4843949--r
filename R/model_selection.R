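#' Enumerate the intrinsic-modulation model space
#'
#' All subsets of hierarchical levels at which superficial-pyramidal
#' self-inhibition may be modulated. Hemispheric pairs toggle together:
#' the A1 level covers lA1 and rA1, STG covers lSTG and rSTG, IFG covers
#' rIFG only. Deterministic order: null model first, then by subset size
#' and lexicographic level order (A1 < STG < IFG).
#'
#' @param levels hierarchical levels (default A1, STG, IFG).
#' @return object of class `model_space`: list of variants, each a list
#'   with `name`, `levels`, `sources` (modulable sources) and `ext_types`
#'   (empty for this space).
#' @export
enumerate_intrinsic_space <- function(levels = c("A1", "STG", "IFG")) {
  level_sources <- list(A1 = c("lA1", "rA1"), STG = c("lSTG", "rSTG"),
                        IFG = "rIFG")
  unknown <- setdiff(levels, names(level_sources))
  if (length(unknown)) {
    stop("unknown level(s): ", paste(unknown, collapse = ", "))
  }
  subsets <- list(character(0))
  for (k in seq_along(levels)) {
    subsets <- c(subsets, utils::combn(levels, k, simplify = FALSE))
  }
  variants <- lapply(subsets, function(ss) {
    list(name = if (length(ss)) paste(ss, collapse = "+") else "null",
         levels = ss,
         sources = unlist(level_sources[ss], use.names = FALSE),
         ext_types = character(0))
  })
  structure(variants, class = "model_space",
            space_type = "intrinsic")
}

#' Enumerate the connection-type model space
#'
#' All subsets of connection types (forward, backward, intrinsic) whose
#' condition-specific modulation is allowed; used for the preliminary
#' deviant-effect comparison. The intrinsic member modulates sp
#' self-inhibition at every source; forward/backward members modulate all
#' extrinsic couplings of that type.
#'
#' @param types connection types (default forward, backward, intrinsic).
#' @param network network whose sources define the intrinsic member.
#' @return a `model_space` (8 variants for 3 types, null included).
#' @export
enumerate_effecttype_space <- function(types = c("forward", "backward",
                                                 "intrinsic"),
                                       network = mmn_network()) {
  unknown <- setdiff(types, c("forward", "backward", "intrinsic"))
  if (length(unknown)) {
    stop("unknown connection type(s): ", paste(unknown, collapse = ", "))
  }
  subsets <- list(character(0))
  for (k in seq_along(types)) {
    subsets <- c(subsets, utils::combn(types, k, simplify = FALSE))
  }
  variants <- lapply(subsets, function(ss) {
    list(name = if (length(ss)) paste(ss, collapse = "+") else "null",
         levels = ss,
         sources = if ("intrinsic" %in% ss) network$sources$name
                   else character(0),
         ext_types = intersect(ss, c("forward", "backward")))
  })
  structure(variants, class = "model_space",
            space_type = "effecttype")
}

#' @export
print.model_space <- function(x, ...) {
  cat("Model space (", attr(x, "space_type"), "): ", length(x),
      " variants: ", paste(vapply(x, `[[`, "", "name"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# complexity rank used for tie-breaking (number of modulated elements)
variant_size <- function(v) length(v$sources) + length(v$ext_types)

#' Fixed-effects Bayesian model selection
#'
#' Compares models by their free energies: log evidences are reported
#' relative to the designated null model, the winner is the model with
#' maximal F (ties broken toward the simpler model and flagged), and the
#' winner's margin over the runner-up is converted to an odds ratio
#' `exp(margin)`. A margin of at least 3 is flagged as strong evidence
#' (about 20:1 odds).
#'
#' @param F_values named numeric vector of free energies (names = model
#'   names) or a list of `inversion_result`s.
#' @param space optional `model_space` (for complexity-aware
#'   tie-breaking); matched by name.
#' @param null_name name of the null/reference model (default `"null"`,
#'   else the first model).
#' @return object of class `bms_result`: data.frame `table` (model, F,
#'   rel_F, n_modulated), `winner`, `runner_up`, `margin`, `odds_ratio`,
#'   `strong`, `tie`.
#' @export
compare_models <- function(F_values, space = NULL, null_name = "null") {
  if (is.list(F_values) && !is.null(F_values[[1]]$F)) {
    F_values <- vapply(F_values, `[[`, numeric(1), "F")
  }
  if (length(F_values) < 2) stop("need at least 2 models to compare")
  if (any(!is.finite(F_values))) stop("non-finite free energies")
  nms <- names(F_values)
  if (is.null(nms)) nms <- paste0("m", seq_along(F_values))
  sizes <- rep(NA_integer_, length(F_values))
  if (!is.null(space)) {
    sizes <- vapply(space, variant_size, integer(1))[
      match(nms, vapply(space, `[[`, "", "name"))]
  }
  null_ix <- if (null_name %in% nms) which(nms == null_name) else 1L
  rel <- F_values - F_values[null_ix]
  ord <- order(-F_values,
               if (all(is.finite(sizes))) sizes else seq_along(F_values))
  best <- ord[1]
  second <- ord[2]
  tie <- abs(F_values[best] - F_values[second]) < 1e-9
  margin <- F_values[best] - F_values[second]
  structure(list(
    table = data.frame(model = nms, F = unname(F_values),
                       rel_F = unname(rel), n_modulated = sizes,
                       stringsAsFactors = FALSE),
    winner = nms[best], runner_up = nms[second],
    margin = unname(margin),
    odds_ratio = unname(exp(min(margin, 700))),
    strong = unname(margin >= 3), tie = tie, null_model = nms[null_ix]),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Fixed-effects Bayesian model selection\n")
  tb <- x$table[order(-x$table$F), ]
  print(tb, row.names = FALSE)
  cat(sprintf("winner: %s (margin %.2f over %s, odds ratio %.1f:1%s%s)\n",
              x$winner, x$margin, x$runner_up, x$odds_ratio,
              if (x$strong) ", strong evidence" else "",
              if (x$tie) ", TIE broken toward simplicity" else ""))
  invisible(x)
}

#' Fit every variant of a model space and select among them
#'
#' @param data projected data (see [project_evoked()]).
#' @param design a [build_factorial_design()].
#' @param space a `model_space`.
#' @param fwd a [forward_setup()].
#' @param base baseline [cmc_parameters()].
#' @param preset prior preset (see [cmc_priors()]).
#' @param ... passed to [fit_multicondition()].
#' @return list with `fits` (named list of `inversion_result`) and `bms`
#'   (a `bms_result`).
#' @export
fit_model_space <- function(data, design, space, fwd,
                            base = cmc_parameters(), preset = "reduced",
                            ...) {
  fits <- lapply(space, function(v) {
    fit_multicondition(data, design, v, fwd, base, preset = preset, ...)
  })
  names(fits) <- vapply(space, `[[`, "", "name")
  bms <- if (length(fits) >= 2) {
    compare_models(fits, space)
  } else {
    # degenerate one-model space: no comparison possible
    structure(list(table = data.frame(model = names(fits),
                                      F = fits[[1]]$F, rel_F = 0,
                                      n_modulated = variant_size(space[[1]]),
                                      stringsAsFactors = FALSE),
                   winner = names(fits), runner_up = NA_character_,
                   margin = NA_real_, odds_ratio = NA_real_,
                   strong = NA, tie = FALSE, null_model = NA_character_),
              class = "bms_result")
  }
  list(fits = fits, bms = bms)
}
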