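#' Feature values of the Feature-Model-Free system
#'
#' The Feature-Model-Free (FMF) learner attaches expected-reward values not
#' to states or actions but to the four environmental features an action can
#' be directed at: environment `E`, lever `L`, magazine `M` and food `F`.
#' The same value is used wherever the feature occurs (approaching the
#' magazine from the CS-onset state and engaging it later both read and
#' write `V(M)`). The value of the food is pinned at 1, the value of the
#' reward itself; it is never learned.
#'
#' @param E,L,M Initial values of the environment, lever and magazine
#'   features. Default 0 (naive agent).
#' @return A named numeric vector over `c("E", "L", "M", "F")` with
#'   `F = 1`, of class `fmf_values`.
#' @examples
#' v <- fmf_values()
#' v["F"]
#' @export
fmf_values <- function(E = 0, L = 0, M = 0) {
  stopifnot(is.numeric(E), is.numeric(L), is.numeric(M))
  structure(c(E = E, L = L, M = M, F = 1), class = "fmf_values")
}

#' Reward-prediction error of the FMF system
#'
#' Computes the temporal-difference error
#' \deqn{\delta = r + \gamma \max_j V(f(s_{t+1}, a_j)) - V(f(s_t, a_t)),}
#' the difference between the observed outcome (immediate reward plus the
#' discounted value of the best feature reachable from the next state) and
#' the previous estimate of the value of the feature the chosen action was
#' directed at. When the transition ends the trial (the eat action) the
#' continuation term is 0, so the eat-transition error is `r - V(f)`.
#'
#' @param values An [fmf_values] vector.
#' @param reward Observed reward, 0 or 1.
#' @param chosen_feature Feature the executed action was directed at
#'   (`"E"`, `"L"`, `"M"` or `"F"`).
#' @param next_features Character vector of features of the actions
#'   available in the successor state, or `NULL` if the trial ended.
#' @param gamma Discount factor in `[0, 1]`.
#' @return The scalar prediction error.
#' @examples
#' v <- fmf_values(E = 0.1, L = 0.5, M = 0.2)
#' fmf_rpe(v, 0, "E", c("L", "E", "M"), gamma = 0.8) # 0.8 * 0.5 - 0.1
#' fmf_rpe(fmf_values(), 1, "F", NULL, gamma = 0.8) # eat: 1 - V(F) = 0
#' @export
fmf_rpe <- function(values, reward, chosen_feature, next_features, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  check_feature(chosen_feature)
  if (is.null(next_features)) {
    continuation <- 0
  } else {
    if (length(next_features) == 0L) {
      stop("a non-terminal successor state must offer at least one action",
        call. = FALSE
      )
    }
    check_feature(next_features)
    continuation <- gamma * max(values[next_features])
  }
  unname(reward + continuation - values[chosen_feature])
}

#' Update a feature value from a prediction error
#'
#' Applies `V(f) <- V(f) + alpha * delta` to the chosen feature. The food
#' feature is exempt: its value stays pinned at 1 regardless of the error.
#'
#' @inheritParams fmf_rpe
#' @param delta Prediction error, typically from [fmf_rpe()].
#' @param alpha Learning rate in `[0, 1]`.
#' @return The updated [fmf_values] vector.
#' @export
fmf_update <- function(values, chosen_feature, delta, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  check_feature(chosen_feature)
  if (chosen_feature != "F") {
    values[chosen_feature] <- values[chosen_feature] + alpha * delta
  }
  values
}

#' Inter-trial-interval value revision
#'
#' During the inter-trial interval (ITI) the animal visits the magazine and
#' explores the environment without being rewarded, which down-revises the
#' values of those two features:
#' `V(M) <- (1 - u_iti) * V(M)` and `V(E) <- (1 - u_iti) * V(E)`.
#' The lever is absent during the ITI and the food value is pinned, so both
#' are untouched. ITI duration is encoded by the size of `u_iti`: a long ITI
#' offers more unrewarded visits and hence a larger revision factor
#' (0.1 versus 0.01 for a short ITI). Applied exactly once per completed
#' trial.
#'
#' @inheritParams fmf_rpe
#' @param u_iti ITI update factor in `[0, 1]`.
#' @return The revised [fmf_values] vector.
#' @export
fmf_iti_revision <- function(values, u_iti) {
  stopifnot(u_iti >= 0, u_iti <= 1)
  values["M"] <- (1 - u_iti) * values["M"]
  values["E"] <- (1 - u_iti) * values["E"]
  values
}

check_feature <- function(f) {
  if (!all(f %in% c("E", "L", "M", "F"))) {
    stop("features must be one of 'E', 'L', 'M', 'F'", call. = FALSE)
  }
  invisible(f)
}

#' @export
print.fmf_values <- function(x, ...) {
  cat("<fmf_values>  ")
  cat(sprintf("%s = %.4g", names(x), unclass(x)), sep = "  ")
  cat("\n")
  invisible(x)
}
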