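#' Build the 2 x 3 factorial design of the MMN group study
#'
#' Six cells (three groups by two stimulus conditions) with five
#' deviation-coded (+1/-1, 0) effect columns: `condition` (deviant vs
#' standard), `risk` (genetic risk: controls vs relatives and patients
#' combined), `diagnosis` (relatives vs patients, controls 0), and the
#' `risk_condition` and `diagnosis_condition` interactions (elementwise
#' products of their parents).
#'
#' @param groups group labels; must be controls, relatives, patients.
#' @param conditions condition labels; must be standard, deviant.
#' @return object of class `factorial_design`: list with `X` (6 x 5 design
#'   matrix, rows named `group.condition`), `groups`, `conditions`,
#'   `cells` (data.frame of group/condition per row).
#' @export
build_factorial_design <- function(groups = c("controls", "relatives",
                                              "patients"),
                                   conditions = c("standard", "deviant")) {
  if (!setequal(groups, c("controls", "relatives", "patients"))) {
    stop("unknown group label(s): ",
         paste(setdiff(groups, c("controls", "relatives", "patients")),
               collapse = ", "))
  }
  if (!setequal(conditions, c("standard", "deviant"))) {
    stop("unknown condition label(s): ",
         paste(setdiff(conditions, c("standard", "deviant")),
               collapse = ", "))
  }
  cells <- expand.grid(condition = conditions, group = groups,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  cond <- ifelse(cells$condition == "deviant", 1, -1)
  risk <- ifelse(cells$group == "controls", -1, 1)
  diag_ <- ifelse(cells$group == "patients", 1,
                  ifelse(cells$group == "relatives", -1, 0))
  X <- cbind(condition = cond, risk = risk, diagnosis = diag_,
             risk_condition = risk * cond,
             diagnosis_condition = diag_ * cond)
  rownames(X) <- paste(cells$group, cells$condition, sep = ".")
  structure(list(X = X, groups = groups, conditions = conditions,
                 cells = cells),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat("2 x", length(x$groups), "factorial design,", ncol(x$X),
      "effect columns:\n")
  print(x$X)
  invisible(x)
}
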