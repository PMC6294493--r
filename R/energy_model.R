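# Nearest-neighbor thermodynamic model: parameter loading and the compiled
# representation handed to the C++ dynamic programs.

GAS_CONSTANT <- 0.0019872  # kcal mol^-1 K^-1
E_INF <- 1e9               # sentinel for forbidden states

PAIR_STRINGS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Construct a nearest-neighbor RNA energy model
#'
#' The `"turner2004"` set is a documented subset of the Turner 2004 rules
#' (Watson-Crick and G·U stacks, hairpin-loop initiations, terminal AU/GU
#' penalties, affine bulge/internal/multiloop penalties; no tetraloop
#' bonuses, mismatches, dangles or coaxial stacking).  The `"uniform-test"`
#' set assigns zero free energy to every structure, so the partition
#' function equals the number of pseudoknot-free structures and all
#' probabilities are rational; it exists for oracle-based testing.
#'
#' Energies are standard free energies at 37 C; the temperature argument
#' only rescales the Boltzmann factor RT (the tables carry no enthalpies).
#'
#' @param parameter_set `"turner2004"`, `"uniform-test"`, or a path to a
#'   parameter table in the plain-text format shipped under
#'   `inst/extdata/params/`.
#' @param temperature kelvin; default 310.15 (37 C).
#' @return an object of class `ensemble_model`.
#' @examples
#' m <- energy_model("uniform-test")
#' m$min_hairpin
#' @export
energy_model <- function(parameter_set = "turner2004", temperature = 310.15) {
  if (identical(parameter_set, "uniform-test")) {
    return(uniform_test_model(temperature))
  }
  path <- if (file.exists(parameter_set)) {
    parameter_set
  } else {
    system.file("extdata", "params", paste0(parameter_set, "-subset.txt"),
                package = "roquinscan", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown parameter set and no such file: ", parameter_set, call. = FALSE)
  }
  parse_param_file(path, temperature)
}

parse_param_file <- function(path, temperature) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  scalars <- list()
  stack <- matrix(E_INF, 6, 6, dimnames = list(PAIR_STRINGS, PAIR_STRINGS))
  hairpin <- rep(NA_real_, 30)
  bulge <- rep(NA_real_, 30)
  internal <- rep(NA_real_, 30)
  pairs <- character()
  for (tk in toks) {
    key <- tk[1L]
    if (key == "stack") {
      stack[tk[2L], tk[3L]] <- as.numeric(tk[4L])
    } else if (key == "hairpin") {
      hairpin[as.integer(tk[2L])] <- as.numeric(tk[3L])
    } else if (key == "bulge") {
      bulge[as.integer(tk[2L])] <- as.numeric(tk[3L])
    } else if (key == "internal") {
      internal[as.integer(tk[2L])] <- as.numeric(tk[3L])
    } else if (key == "pairs") {
      pairs <- tk[-1L]
    } else if (key == "name") {
      scalars$name <- tk[2L]
    } else {
      scalars[[key]] <- as.numeric(tk[2L])
    }
  }
  stopifnot(all(pairs %in% PAIR_STRINGS))
  RT <- GAS_CONSTANT * temperature
  js <- 1.75 * RT
  # Jacobson-Stockmayer extrapolation from the last tabulated length
  extrapolate <- function(v) {
    last <- max(which(!is.na(v)))
    for (L in seq_len(30)) {
      if (L > last) v[L] <- v[last] + js * log(L / last)
    }
    v
  }
  hairpin <- extrapolate(hairpin)
  bulge <- extrapolate(bulge)
  internal[1L] <- E_INF
  internal <- extrapolate(internal)
  model <- list(
    parameter_set = scalars$name %||% basename(path),
    temperature = temperature,
    gas_constant = GAS_CONSTANT,
    pairs = pairs,
    stack = stack,
    hairpin = hairpin,
    bulge = bulge,
    internal = internal,
    terminal_au = scalars$terminal_au,
    ml_closing = scalars$ml_closing,
    ml_branch = scalars$ml_branch,
    ml_unpaired = scalars$ml_unpaired,
    asym_coef = scalars$asym_coef,
    asym_max = scalars$asym_max,
    min_hairpin = as.integer(scalars$min_hairpin),
    max_internal = as.integer(scalars$max_internal),
    js_coef = js,
    RT = RT
  )
  model$compiled <- compile_model(model)
  structure(model, class = "ensemble_model")
}

uniform_test_model <- function(temperature = 310.15) {
  RT <- GAS_CONSTANT * temperature
  stack <- matrix(0, 6, 6, dimnames = list(PAIR_STRINGS, PAIR_STRINGS))
  model <- list(
    parameter_set = "uniform-test",
    temperature = temperature,
    gas_constant = GAS_CONSTANT,
    pairs = PAIR_STRINGS,
    stack = stack,
    hairpin = rep(0, 30),
    bulge = rep(0, 30),
    internal = rep(0, 30),
    terminal_au = 0,
    ml_closing = 0,
    ml_branch = 0,
    ml_unpaired = 0,
    asym_coef = 0,
    asym_max = 0,
    min_hairpin = 3L,
    max_internal = 30L,
    js_coef = 0,
    RT = RT
  )
  model$hairpin[seq_len(2L)] <- 0  # lengths < min_hairpin are blocked by geometry
  model$compiled <- compile_model(model)
  structure(model, class = "ensemble_model")
}

BASE_CODES <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)

encode_seq <- function(s) unname(BASE_CODES[seq_chars(s)])

compile_model <- function(model) {
  pair_ok <- integer(25)
  au <- numeric(25)
  for (p in model$pairs) {
    a <- BASE_CODES[substr(p, 1, 1)]; b <- BASE_CODES[substr(p, 2, 2)]
    pair_ok[a * 5 + b + 1] <- 1L
    if (p %in% c("AU", "UA", "GU", "UG")) au[a * 5 + b + 1] <- model$terminal_au
  }
  stk <- rep(E_INF, 625)
  for (p in model$pairs) for (q in model$pairs) {
    a <- BASE_CODES[substr(p, 1, 1)]; b <- BASE_CODES[substr(p, 2, 2)]
    cc <- BASE_CODES[substr(q, 1, 1)]; d <- BASE_CODES[substr(q, 2, 2)]
    stk[((a * 5 + b) * 5 + cc) * 5 + d + 1] <- model$stack[p, q]
  }
  # vectors are indexed by loop length in C++ (position L+1 here)
  hp <- numeric(31); hp[] <- E_INF
  for (L in model$min_hairpin:30) hp[L + 1] <- model$hairpin[L]
  bg <- numeric(31); bg[] <- E_INF
  for (L in 1:30) bg[L + 1] <- model$bulge[L]
  itl <- numeric(31); itl[] <- E_INF
  for (L in 2:30) itl[L + 1] <- model$internal[L]
  list(
    pair_ok = pair_ok, stack = stk, au = au,
    hairpin = hp, bulge = bg, internal = itl,
    asym_coef = model$asym_coef, asym_max = model$asym_max,
    js_coef = model$js_coef,
    ml_a = model$ml_closing, ml_b = model$ml_branch, ml_c = model$ml_unpaired,
    min_hairpin = model$min_hairpin, max_loop = model$max_internal,
    RT = model$RT
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model '%s': T = %.2f K, pairs = %s, min hairpin loop = %d>\n",
              x$parameter_set, x$temperature, paste(x$pairs, collapse = "/"),
              x$min_hairpin))
  invisible(x)
}

#' Model pairing predicate (includes G·U when the parameter set allows it)
#' @param model an `ensemble_model`.
#' @param a,b upper-case bases.
#' @return logical vector.
#' @export
model_can_pair <- function(model, a, b) {
  paste0(a, b) %in% model$pairs
}
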