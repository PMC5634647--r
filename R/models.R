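#' Specify a candidate behavioural model
#'
#' Builds the description of one candidate model: which weight structure
#' mixes the two value systems, which parameters are free versus fixed, and
#' which transform carries each free parameter to the unconstrained scale
#' used by the hierarchical fit (logistic for `[0,1]` parameters,
#' exponential for `beta`, identity for the stay bias).
#'
#' @param weight_structure `"pure_MF"` (weight fixed at 0), `"pure_MB"`
#'   (fixed at 1), `"hybrid_1w"` (one free weight), `"hybrid_3block"` (one
#'   free weight per 200-trial block) or `"hybrid_3freq"` (one free weight
#'   per contingency-change-frequency class: fast/medium/slow).
#' @param control Control hybrids mixing two systems of the same kind with
#'   small (0.25) and large (0.75) fixed learning rates: `"mf_mf"` (two
#'   model-free systems, shared free eligibility trace), `"mf_mf_lambda"`
#'   (two model-free systems with eligibility traces fixed at 0 and 1) or
#'   `"mb_mb"` (two model-based systems). The weight then mixes the two
#'   control systems.
#' @param stay_bias Include a free stay-bias parameter (FALSE fixes it at 0).
#' @param fictive Apply mirrored (fictive) updates to unvisited states.
#' @param lam_fixed `NULL` (free eligibility trace) or a value to fix it at
#'   (ablations use 0 or 1).
#' @param single_learning_rate Share one learning rate between the
#'   model-free and model-based systems.
#' @param free_transition_rate Free the model-based transition learning
#'   rate `alpha_T` (otherwise fixed at 1).
#' @param fixed Named list of additional natural-scale values to fix, e.g.
#'   `list(alpha_MF = 0.5)`; used to build reduced models for tests.
#' @param name Optional model name; a descriptive default is built.
#'
#' @return A `flexmb_model_spec` with the free-parameter table
#'   (`$param_table`: name, transform, fixed value or `NA`).
#' @export
#' @examples
#' model_spec("hybrid_3block")$param_table
model_spec <- function(weight_structure = c("hybrid_1w", "pure_MF", "pure_MB",
                                            "hybrid_3block", "hybrid_3freq"),
                       control = c("none", "mf_mf", "mf_mf_lambda", "mb_mb"),
                       stay_bias = TRUE,
                       fictive = TRUE,
                       lam_fixed = NULL,
                       single_learning_rate = FALSE,
                       free_transition_rate = FALSE,
                       fixed = list(),
                       name = NULL) {
  weight_structure <- match.arg(weight_structure)
  control <- match.arg(control)
  if (control != "none" && weight_structure %in% c("pure_MF", "pure_MB")) {
    stop("control hybrids need a free mixing weight")
  }

  row <- function(nm, tr, fx = NA_real_) {
    tibble::tibble(name = nm, transform = tr, fixed = fx)
  }
  tab <- switch(weight_structure,
    pure_MF = row("w", "logit", 0),
    pure_MB = row("w", "logit", 1),
    hybrid_1w = row("w", "logit"),
    hybrid_3block = ,
    hybrid_3freq = dplyr::bind_rows(row("w1", "logit"), row("w2", "logit"),
                                    row("w3", "logit"))
  )
  if (control == "none") {
    if (weight_structure != "pure_MB") {
      if (single_learning_rate) {
        tab <- dplyr::bind_rows(tab, row("alpha", "logit"))
      } else {
        tab <- dplyr::bind_rows(tab, row("alpha_MF", "logit"))
      }
      lam_fx <- if (is.null(lam_fixed)) NA_real_ else as.numeric(lam_fixed)
      tab <- dplyr::bind_rows(tab, row("lam", "logit", lam_fx))
    }
    if (weight_structure != "pure_MF" && !single_learning_rate) {
      tab <- dplyr::bind_rows(tab, row("alpha_MB", "logit"))
    }
    if (weight_structure != "pure_MF" && free_transition_rate) {
      tab <- dplyr::bind_rows(tab, row("alpha_T", "logit"))
    }
  } else if (control == "mf_mf") {
    lam_fx <- if (is.null(lam_fixed)) NA_real_ else as.numeric(lam_fixed)
    tab <- dplyr::bind_rows(tab, row("lam", "logit", lam_fx))
  }
  tab <- dplyr::bind_rows(tab, row("beta", "log"),
                          row("stay", "identity", if (stay_bias) NA_real_ else 0))
  # user-imposed fixings
  for (nm in names(fixed)) {
    if (!nm %in% tab$name) stop("cannot fix unknown parameter: ", nm)
    tab$fixed[tab$name == nm] <- fixed[[nm]]
  }

  if (is.null(name)) {
    name <- if (control != "none") paste0("control_", control) else weight_structure
    if (!fictive) name <- paste0(name, "_nofictive")
    if (!stay_bias) name <- paste0(name, "_nostay")
    if (!is.null(lam_fixed)) name <- paste0(name, "_lam", lam_fixed)
    if (single_learning_rate) name <- paste0(name, "_1alpha")
    if (free_transition_rate) name <- paste0(name, "_freeT")
  }
  structure(
    list(name = name, weight_structure = weight_structure, control = control,
         fictive = fictive, single_learning_rate = single_learning_rate,
         free_transition_rate = free_transition_rate,
         param_table = tab),
    class = "flexmb_model_spec"
  )
}

#' @export
print.flexmb_model_spec <- function(x, ...) {
  cat("<flexmb_model_spec>", x$name, "\n")
  free <- x$param_table$name[is.na(x$param_table$fixed)]
  cat("  free parameters:", paste(free, collapse = ", "), "\n")
  invisible(x)
}

spec_free_names <- function(spec) {
  spec$param_table$name[is.na(spec$param_table$fixed)]
}

spec_free_transforms <- function(spec) {
  tab <- spec$param_table
  stats::setNames(tab$transform[is.na(tab$fixed)], tab$name[is.na(tab$fixed)])
}

#' Map parameters between natural and unconstrained scales
#'
#' `transform_params()` carries a named natural-scale free-parameter vector
#' to the unconstrained scale the Gaussian group prior lives on (logit for
#' `[0,1]` parameters, log for `beta`, identity for the stay bias);
#' `untransform_params()` is its exact inverse. Natural values at the
#' boundary of a logit- or log-transformed range are rejected because they
#' have no finite unconstrained image.
#'
#' @param spec A [model_spec()].
#' @param x Named numeric vector over the spec's free parameters (natural
#'   scale for `transform_params`, unconstrained for `untransform_params`).
#' @return Named numeric vector on the other scale.
#' @export
transform_params <- function(spec, x) {
  tr <- spec_free_transforms(spec)
  x <- x[names(tr)]
  out <- x
  for (nm in names(tr)) {
    out[nm] <- switch(tr[nm],
      logit = {
        if (x[nm] <= 0 || x[nm] >= 1) stop("boundary value for ", nm)
        qlogis(x[nm])
      },
      log = {
        if (x[nm] <= 0) stop("boundary value for ", nm)
        log(x[nm])
      },
      identity = x[nm]
    )
  }
  out
}

#' @rdname transform_params
#' @export
untransform_params <- function(spec, x) {
  tr <- spec_free_transforms(spec)
  x <- x[names(tr)]
  out <- x
  for (nm in names(tr)) {
    out[nm] <- switch(tr[nm],
      logit = plogis(x[nm]),
      log = exp(x[nm]),
      identity = x[nm]
    )
  }
  out
}

# full natural-scale parameter list (free values merged with fixed ones)
spec_full_params <- function(spec, free) {
  tab <- spec$param_table
  vals <- stats::setNames(tab$fixed, tab$name)
  vals[names(free)] <- free
  as.list(vals)
}

# engine parameter vector for the C++ core; layout (1-based):
# 1-3 weight components, 4-7 system 1 (type, alpha, lam, alphaT),
# 8-11 system 2, 12 beta, 13 stay, 14 fictive flag
engine_args <- function(spec, full) {
  wvec <- if (spec$weight_structure %in% c("hybrid_3block", "hybrid_3freq")) {
    c(full$w1, full$w2, full$w3)
  } else {
    rep(full$w, 3)
  }
  if (spec$control == "none") {
    a_mb <- if (spec$single_learning_rate) full$alpha else full$alpha_MB
    a_mf <- if (spec$single_learning_rate) full$alpha else full$alpha_MF
    aT <- if (spec$free_transition_rate) full$alpha_T else 1
    lam <- if (is.null(full$lam) || is.na(full$lam)) 0 else full$lam
    if (is.null(a_mb) || is.na(a_mb)) a_mb <- 0.5 # unused under pure_MF (w = 0)
    if (is.null(a_mf) || is.na(a_mf)) a_mf <- 0.5 # unused under pure_MB (w = 1)
    c(wvec, 1, a_mb, 0, aT, 0, a_mf, lam, 1,
      full$beta, full$stay, as.numeric(spec$fictive))
  } else {
    sys_type <- if (spec$control == "mb_mb") 1 else 0
    lam1 <- if (spec$control == "mf_mf_lambda") 0 else if (is.na(full$lam %||% NA)) 0 else full$lam
    lam2 <- if (spec$control == "mf_mf_lambda") 1 else lam1
    c(wvec, sys_type, 0.25, lam1, 1, sys_type, 0.75, lam2, 1,
      full$beta, full$stay, as.numeric(spec$fictive))
  }
}

# slots of the engine vector that each free parameter occupies
engine_positions <- function(spec, name) {
  if (name %in% c("w", "w1", "w2", "w3")) {
    return(switch(name, w = 1:3, w1 = 1L, w2 = 2L, w3 = 3L))
  }
  if (spec$control == "none") {
    switch(name,
      alpha_MB = 5L, alpha_T = 7L, alpha_MF = 9L, alpha = c(5L, 9L),
      lam = 10L, beta = 12L, stay = 13L,
      stop("no engine slot for ", name))
  } else {
    switch(name,
      lam = c(6L, 10L), beta = 12L, stay = 13L,
      stop("no engine slot for ", name))
  }
}

# fast closure: unconstrained free vector -> choice NLL for one encoded
# subject (the hot path of the E-step)
make_subject_nll_fun <- function(enc, spec) {
  free <- spec_free_names(spec)
  tr <- spec_free_transforms(spec)
  logit_i <- which(unname(tr) == "logit")
  log_i <- which(unname(tr) == "log")
  dummy <- stats::setNames(rep(0.5, length(free)), free)
  dummy[tr == "log"] <- 1
  template <- engine_args(spec, spec_full_params(spec, as.list(dummy)))
  pos <- lapply(free, function(nm) engine_positions(spec, nm))
  force(enc)
  function(x) {
    v <- x
    if (length(logit_i)) v[logit_i] <- plogis(x[logit_i])
    if (length(log_i)) v[log_i] <- exp(x[log_i])
    e <- template
    for (j in seq_along(pos)) e[pos[[j]]] <- v[j]
    cpp_nll(enc$start, enc$choice, enc$s2, enc$term, enc$reward, enc$w_idx, e)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# which component of the weight vector governs each trial
w_index_for <- function(spec, block, group) {
  switch(spec$weight_structure,
    hybrid_3block = as.integer(block),
    hybrid_3freq = {
      # group 1: fast, medium, slow block order; group 2: medium, fast, slow
      map1 <- c(1L, 2L, 3L)
      map2 <- c(2L, 1L, 3L)
      ifelse(group == 1L, map1[block], map2[block])
    },
    rep(1L, length(block))
  )
}

# encode a trial-log tibble into the integer arrays the engine consumes
encode_dataset <- function(data, spec) {
  list(
    start = match(data$start_state, .start_levels) - 1L,
    choice = dplyr::coalesce(match(data$first_choice, .action_levels) - 1L, -1L),
    s2 = dplyr::coalesce(match(data$second_state, .second_levels) - 1L, -1L),
    term = dplyr::coalesce(match(data$terminal_state, .terminal_levels) - 1L, -1L),
    reward = as.numeric(data$reward),
    w_idx = w_index_for(
      spec, data$block,
      if ("group" %in% names(data)) data$group else rep(1L, nrow(data))) - 1L
  )
}
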