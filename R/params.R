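#' Structural and elastic parameters of DNA forms
#'
#' Loads the per-state parameter table of the four double-helix forms
#' (B, L, P, S).  The packaged defaults hold the commonly used literature
#' values: bending/twisting persistence lengths, contour ratio (base-pair rise
#' relative to B), helical repeat, handedness, base-pairing energy relative to
#' B, and the Fuller-correction weight lambda.
#'
#' @param file Optional path to a YAML parameter file with the same layout as
#'   the packaged default (`system.file("extdata", "dna_states.yaml",
#'   package = "twlc")`).  `NULL` loads the defaults.
#' @return A `dna_params` object: data frame with one row per state
#'   (rownames B/L/P/S) and columns `Lp`, `Ltw`, `contour_ratio`, `h`,
#'   `handedness`, `mu`, `lam`; attribute `rise_B` holds the B-DNA base-pair
#'   rise in nm.
#' @export
#' @examples
#' p <- dna_state_params()
#' p["L", "h"]  # 16 bp per turn
dna_state_params <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "dna_states.yaml", package = "twlc")
  }
  raw <- yaml::read_yaml(file)
  if (is.null(raw$states)) stop("parameter file has no 'states' entry: ", file)
  tab <- do.call(rbind, lapply(raw$states, function(s) {
    as.data.frame(s[c("Lp", "Ltw", "contour_ratio", "h", "handedness",
                      "mu", "lam")])
  }))
  rownames(tab) <- names(raw$states)
  attr(tab, "rise_B") <- if (is.null(raw$rise_B_nm)) 0.33 else raw$rise_B_nm
  class(tab) <- c("dna_params", "data.frame")
  validate_dna_params(tab)
  tab
}

validate_dna_params <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("Lp", "Ltw", "contour_ratio", "h", "handedness", "mu", "lam")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  with(tab, {
    if (any(Lp <= 0) || any(Ltw <= 0) || any(h <= 0) || any(contour_ratio <= 0))
      stop("Lp, Ltw, h and contour_ratio must all be positive")
    if (!all(handedness %in% c(-1, 1)))
      stop("handedness must be +1 (right-handed) or -1 (left-handed)")
  })
  if ("B" %in% rownames(tab)) {
    b <- tab["B", ]
    if (b$mu != 0 || b$handedness != 1 || b$contour_ratio != 1)
      stop("state B is the reference: mu = 0, handedness = +1, contour_ratio = 1")
  }
  invisible(tab)
}

#' Write a parameter table to YAML
#'
#' @param params A `dna_params` table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_dna_params <- function(params, file) {
  validate_dna_params(params)
  states <- lapply(seq_len(nrow(params)), function(i) as.list(params[i, ]))
  names(states) <- rownames(params)
  yaml::write_yaml(list(rise_B_nm = attr(params, "rise_B"), states = states),
                   file)
  invisible(file)
}

state_row <- function(u, params) {
  if (length(u) != 1L || !u %in% rownames(params)) {
    stop("unknown DNA state id: '", u, "' (have: ",
         paste(rownames(params), collapse = ", "), ")")
  }
  params[u, ]
}

#' Relaxed linking-number density of a DNA form
#'
#' Difference in relaxed linking number per base pair between state `u` and
#' the B reference: `dlk0(u) = handedness_u / h_u - 1 / h_B`, where `h` is the
#' helical repeat in bp per turn and the sign is positive for right-handed
#' helices.  For B the result is exactly zero.
#'
#' @param u State id (`"B"`, `"L"`, `"P"` or `"S"`).
#' @param params Parameter table from [dna_state_params()].
#' @return Relaxed linking density in turns per bp.
#' @export
#' @examples
#' relaxed_linking_density("L")  # about -0.159
relaxed_linking_density <- function(u, params = dna_state_params()) {
  if (identical(u, "B")) return(0)
  s <- state_row(u, params)
  hB <- state_row("B", params)$h
  s$handedness / s$h - 1 / hB
}

#' Discretized chain geometry
#'
#' Splits a DNA of `n_bp` base pairs into `N = round(n_bp / q)` rigid
#' segments of `q` bp each.  The segment length in state `u` is
#' `b_u = q * contour_ratio_u * rise_B` nm.  Segments must stay short against
#' both persistence lengths of every enabled state (`b_u <= Lp_u / 5`
#' enforced), otherwise the discrete elastic energy misrepresents the
#' continuous rod.
#'
#' @param n_bp Total number of base pairs.
#' @param q Base pairs per segment (real valued; default 1.5).
#' @param params Parameter table.
#' @param states Which states the chain may occupy (validity is checked for
#'   these only).
#' @return A `chain_spec` object: list with `n_bp`, `q`, `n_segments`,
#'   `b` (named vector of segment lengths, nm), `Lk0_B` (relaxed linking
#'   number of the whole B-DNA).
#' @export
chain_spec <- function(n_bp, q = 1.5, params = dna_state_params(),
                       states = rownames(params)) {
  stopifnot(n_bp >= 2, q > 0)
  rise <- attr(params, "rise_B")
  n_seg <- as.integer(round(n_bp / q))
  if (n_seg < 2) stop("chain must have at least 2 segments")
  b <- q * params[states, "contour_ratio"] * rise
  names(b) <- states
  bad <- states[b > params[states, "Lp"] / 5]
  if (length(bad)) {
    stop("segment length exceeds Lp/5 for state(s): ",
         paste(bad, collapse = ", "), "; reduce q")
  }
  Lk0_B <- n_bp / state_row("B", params)$h
  structure(list(n_bp = n_bp, q = q, n_segments = n_seg, b = b,
                 Lk0_B = Lk0_B),
            class = "chain_spec")
}

#' Dimensionless segment stiffness
#'
#' Bending and twisting stiffness of one segment in state `u`:
#' `a = Lp / b_u` and `c = Ltw / b_u`.
#'
#' @param u State id.
#' @param chain A [chain_spec()].
#' @param params Parameter table.
#' @return List with elements `a` and `c`.
#' @export
dimensionless_stiffness <- function(u, chain, params = dna_state_params()) {
  s <- state_row(u, params)
  b <- chain$b[[u]]
  if (is.null(b) || !is.finite(b) || b <= 0) {
    stop("no positive segment length for state '", u, "' in chain spec")
  }
  list(a = s$Lp / b, c = s$Ltw / b)
}
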