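#' Prior dominance history for starting-rating initialization
#'
#' Bundles prior knowledge of the hierarchy, used by [elo_seq()] (via
#' [starting_ratings()]) to set individual starting Elo-ratings instead of
#' starting every individual at the common baseline. Supplying even a rough
#' prior ranking shortens, and can eliminate, the burn-in period during
#' which ratings started from a common value do not yet reflect true
#' relative positions.
#'
#' Three forms of prior are supported, processed in order of preference:
#'
#' 1. `prior_elo` — explicit Elo-ratings carried over from an earlier
#'    analysis, e.g. `c(DN = 1500, ZF = 1200)`; used as given.
#' 2. `prior_ranks` — ordinal ranks with 1 the most dominant, e.g.
#'    `c(DN = 1, ZF = 2)`; ties are allowed and tied individuals receive
#'    identical starting ratings.
#' 3. `prior_categories` — ordered rank categories `"alpha"`, `"high"`,
#'    `"medium"`, `"low"`, e.g. `c(DN = "alpha", MA = "low")`; converted to
#'    ordinal ranks by [category_ranks()] before initialization.
#'
#' If the preferred form is present the others are ignored. Individuals in
#' the analysis but absent from the prior mapping start at exactly
#' `starting_value`. Identifiers are case-sensitive and must match the
#' interaction record.
#'
#' @param prior_elo Optional named numeric vector of prior Elo-ratings.
#' @param prior_ranks Optional named numeric vector of ordinal ranks
#'   (all `>= 1`; 1 = most dominant; ties allowed).
#' @param prior_categories Optional named character vector with values in
#'   `alpha`, `high`, `medium`, `low`.
#' @param starting_value Baseline starting rating `S_e` (default 1000).
#' @param k Positive constant `K` used in the initialization formula and as
#'   the default per-interaction K (default 200).
#' @param rank_index Reciprocal-power spreading index `I_r >= 0`
#'   (default 0). Larger values stretch the top-ranked individual away from
#'   the rest while compressing differences among low ranks; 0 gives evenly
#'   spaced starting ratings `k` points apart for consecutive ranks.
#' @return An object of class `elo_priors`.
#' @examples
#' elo_priors(prior_ranks = c(a = 1, b = 2, c = 3), rank_index = 0.3)
#' @seealso [starting_ratings()], [read_prior_config()]
#' @export
elo_priors <- function(prior_elo = NULL, prior_ranks = NULL,
                       prior_categories = NULL,
                       starting_value = 1000, k = 200, rank_index = 0) {
  check_named <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (is.list(v)) v <- unlist(v)
    if (!length(v)) return(NULL)
    if (is.null(names(v)) || any(names(v) == "")) {
      stop("'", what, "' must be a named vector (id = value)", call. = FALSE)
    }
    if (anyDuplicated(names(v))) {
      stop("duplicate id in '", what, "': ",
           names(v)[duplicated(names(v))][1], call. = FALSE)
    }
    v
  }
  prior_elo <- check_named(prior_elo, "prior_elo")
  prior_ranks <- check_named(prior_ranks, "prior_ranks")
  prior_categories <- check_named(prior_categories, "prior_categories")

  if (!is.null(prior_elo) && !is.numeric(prior_elo)) {
    stop("'prior_elo' must be numeric", call. = FALSE)
  }
  if (!is.null(prior_ranks)) {
    if (!is.numeric(prior_ranks) || any(prior_ranks < 1)) {
      stop("'prior_ranks' must be numeric ordinal ranks >= 1", call. = FALSE)
    }
  }
  if (!is.null(prior_categories)) {
    prior_categories <- structure(tolower(as.character(prior_categories)),
                                  names = names(prior_categories))
    bad <- setdiff(unique(prior_categories),
                   c("alpha", "high", "medium", "low"))
    if (length(bad)) {
      stop("unknown rank category '", bad[1],
           "' (expected alpha/high/medium/low)", call. = FALSE)
    }
  }
  if (!is.numeric(starting_value) || length(starting_value) != 1L ||
      !is.finite(starting_value)) {
    stop("'starting_value' must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("'k' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(rank_index) || length(rank_index) != 1L ||
      !is.finite(rank_index) || rank_index < 0) {
    stop("'rank_index' (I_r) must be a single number >= 0", call. = FALSE)
  }

  structure(list(prior_elo = prior_elo, prior_ranks = prior_ranks,
                 prior_categories = prior_categories,
                 starting_value = starting_value, k = k,
                 rank_index = rank_index),
            class = "elo_priors")
}

#' @export
print.elo_priors <- function(x, ...) {
  cat("Prior dominance history\n")
  cat("  starting value:", x$starting_value,
      " K:", x$k, " rank index (I_r):", x$rank_index, "\n")
  kind <- if (!is.null(x$prior_elo)) {
    sprintf("explicit Elo-ratings for %d individual(s)", length(x$prior_elo))
  } else if (!is.null(x$prior_ranks)) {
    sprintf("ordinal ranks for %d individual(s)", length(x$prior_ranks))
  } else if (!is.null(x$prior_categories)) {
    sprintf("rank categories for %d individual(s)",
            length(x$prior_categories))
  } else "none (all individuals start at the baseline)"
  cat("  prior:", kind, "\n")
  invisible(x)
}

#' Convert ordered rank categories to ordinal ranks
#'
#' Maps the ordered categories `alpha`, `high`, `medium`, `low` to the
#' ordinal ranks `1`, `N/4`, `N/2`, and `N - N/4`, where `N` is the total
#' number of subjects in the analysis. This spreads the four categories
#' evenly across the rank range; fractional ranks are kept unrounded so
#' that the starting-rating formula sees no spurious ties.
#'
#' @param categories Named character vector, id to category.
#' @param n_subjects Total number of subjects `N` in the analysis (not just
#'   those listed in `categories`).
#' @return Named numeric vector of ordinal ranks for the listed ids.
#' @examples
#' category_ranks(c(a = "alpha", b = "high", c = "medium", d = "low"), 14)
#' @export
category_ranks <- function(categories, n_subjects) {
  if (!length(categories)) stop("'categories' is empty", call. = FALSE)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    stop("'n_subjects' must be a count >= 1", call. = FALSE)
  }
  if (is.null(names(categories)) || anyDuplicated(names(categories))) {
    stop("'categories' must be uniquely named by id", call. = FALSE)
  }
  categories <- tolower(as.character(categories)) |>
    stats::setNames(names(categories))
  lut <- c(alpha = 1, high = n_subjects / 4, medium = n_subjects / 2,
           low = n_subjects - n_subjects / 4)
  bad <- setdiff(unique(categories), names(lut))
  if (length(bad)) {
    stop("unknown rank category '", bad[1], "'", call. = FALSE)
  }
  stats::setNames(unname(lut[categories]), names(categories))
}

#' Starting Elo-ratings from prior history
#'
#' Computes each individual's starting Elo-rating from an [elo_priors()]
#' specification. Explicit prior Elo-ratings are used as given. For ordinal
#' (or categorical, after [category_ranks()] conversion) priors, the raw
#' starting rating of individual `i` with prior rank `S_ri` is
#'
#' \deqn{E_i = S_e + (x_r - S_{ri}) \cdot K \cdot S_{ri}^{-I_r}}
#'
#' where `x_r` is the median of the supplied ranks. At `I_r = 0` this
#' spaces consecutive ranks exactly `K` points apart; larger `I_r` values
#' stretch the top-ranked individual away from the rest while compressing
#' the low ranks. The raw ratings are then recentred by a common shift so
#' their mean equals `S_e` (a no-op in the symmetric complete-rank case at
#' `I_r = 0`); individuals without a prior receive `S_e` exactly.
#'
#' @param priors An [elo_priors()] object.
#' @param roster Character vector of all individuals in the analysis.
#' @return Named numeric vector of starting ratings, one per roster id.
#' @examples
#' starting_ratings(elo_priors(prior_ranks = c(a = 1, b = 2, c = 3, d = 4,
#'                                             e = 5)),
#'                  roster = letters[1:5])
#' @export
starting_ratings <- function(priors, roster) {
  stopifnot(inherits(priors, "elo_priors"))
  roster <- as.character(roster)
  if (!length(roster)) stop("'roster' is empty", call. = FALSE)
  if (anyDuplicated(roster)) stop("duplicate id in roster", call. = FALSE)
  s_e <- priors$starting_value
  out <- stats::setNames(rep(s_e, length(roster)), roster)

  check_roster <- function(ids, what) {
    extra <- setdiff(ids, roster)
    if (length(extra)) {
      stop("id '", extra[1], "' in ", what, " is not in the roster",
           call. = FALSE)
    }
  }

  if (!is.null(priors$prior_elo)) {
    check_roster(names(priors$prior_elo), "prior_elo")
    out[names(priors$prior_elo)] <- priors$prior_elo
    return(out)
  }

  ranks <- priors$prior_ranks
  if (is.null(ranks) && !is.null(priors$prior_categories)) {
    check_roster(names(priors$prior_categories), "prior_categories")
    ranks <- category_ranks(priors$prior_categories, length(roster))
  }
  if (is.null(ranks)) return(out)

  check_roster(names(ranks), "prior ranks")
  x_r <- stats::median(ranks)
  raw <- s_e + (x_r - ranks) * priors$k * ranks^(-priors$rank_index)
  raw <- raw + (s_e - mean(raw))   # centre ranked ids on S_e
  out[names(ranks)] <- raw
  out
}

#' Read a prior-history configuration file
#'
#' Reads an [elo_priors()] specification from a YAML file: a flat key-value
#' document with optional scalar keys `starting_value`, `k`, `rank_index`
#' and optional mapping sections `prior_elo`, `prior_ranks`,
#' `prior_categories` (ids as keys, case-sensitive). The argument names of
#' the underlying R function family (`startingvalue`, `constant_k`,
#' `priorRankIndex`, `priorElo`, `priorRanks`, `priorRankCategory`) are
#' accepted as aliases. Unknown keys are an error, so typos do not pass
#' silently.
#'
#' @param path Path to the YAML file.
#' @return An [elo_priors()] object with defaults applied for absent keys.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("rank_index: 0.3", "prior_ranks:", "  DN: 1", "  ZF: 2"), f)
#' read_prior_config(f)
#' @export
read_prior_config <- function(path) {
  if (!file.exists(path)) {
    stop("prior config file not found: ", path, call. = FALSE)
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed prior config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop("malformed prior config: expected key-value mappings", call. = FALSE)
  }
  aliases <- c(starting_value = "starting_value",
               startingvalue = "starting_value",
               k = "k", constant_k = "k",
               rank_index = "rank_index", priorrankindex = "rank_index",
               prior_rank_index = "rank_index",
               prior_elo = "prior_elo", priorelo = "prior_elo",
               prior_ranks = "prior_ranks", priorranks = "prior_ranks",
               prior_categories = "prior_categories",
               priorrankcategory = "prior_categories",
               prior_rank_category = "prior_categories")
  keys <- tolower(names(cfg))
  unknown <- which(!keys %in% names(aliases))
  if (length(unknown)) {
    stop("unknown key '", names(cfg)[unknown[1]], "' in prior config",
         call. = FALSE)
  }
  canon <- aliases[keys]
  if (anyDuplicated(canon)) {
    stop("duplicate key '", names(cfg)[duplicated(canon)][1],
         "' in prior config", call. = FALSE)
  }
  args <- stats::setNames(cfg, canon)
  as_map <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (!is.list(v) && is.null(names(v))) {
      stop("section '", what, "' must map ids to values", call. = FALSE)
    }
    unlist(v)
  }
  elo_priors(
    prior_elo = as_map(args$prior_elo, "prior_elo"),
    prior_ranks = as_map(args$prior_ranks, "prior_ranks"),
    prior_categories = as_map(args$prior_categories, "prior_categories"),
    starting_value = args$starting_value %||% 1000,
    k = args$k %||% 200,
    rank_index = args$rank_index %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
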