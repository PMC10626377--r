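#' Nuclear decay data: nuclides, emissions and decay chains
#'
#' The decay substrate for the dosimetry layer. A `nuclide` holds a half-life,
#' a per-disintegration emission table (kind, mean energy in MeV, yield) and
#' its decay modes (daughter, branching fraction). A `decay_chain` is the
#' directed acyclic graph of all progeny reachable from a parent, ending at a
#' stable terminal nuclide. The bundled fixture covers Lu-177 (stable daughter
#' Hf-177) and the Ac-225 series, including the Bi-213 branch point (beta route
#' through Po-213, alpha route through Tl-209), truncated at Bi-209.
#'
#' @name decay-data
NULL

EMISSION_KINDS <- c("alpha", "beta_mean", "conversion_electron", "auger",
                    "gamma", "xray")

# Emission-filter modes. `reference` reproduces the printed dose-constant
# pair: locally absorbed radiation only -- alphas plus beta continuum mean
# energies; photons always excluded from self-dose (absorbed fraction ~0 for
# mm-scale tumors). `charged_all` additionally counts conversion and Auger
# electrons and deviates from the reference constants by construction.
EMISSION_FILTERS <- list(
  reference            = c("alpha", "beta_mean"),
  charged_all          = c("alpha", "beta_mean", "conversion_electron", "auger"),
  beta_continuum_only  = "beta_mean",
  alpha_only           = "alpha",
  all_photons_only     = c("gamma", "xray"),
  all                  = EMISSION_KINDS
)

resolve_emission_filter <- function(emission_filter) {
  if (is.character(emission_filter) && length(emission_filter) == 1 &&
      emission_filter %in% names(EMISSION_FILTERS)) {
    return(EMISSION_FILTERS[[emission_filter]])
  }
  if (all(emission_filter %in% EMISSION_KINDS)) return(emission_filter)
  stop("unknown emission filter: ", paste(emission_filter, collapse = ", "))
}

#' Canonicalise a nuclide name
#'
#' Accepts `"Ac-225"`, `"225Ac"`, `"ac225"` etc. and returns the canonical
#' `"Ac-225"` form used in the bundled tables.
#'
#' @param name character vector of nuclide labels.
#' @return canonical names.
#' @export
normalize_nuclide <- function(name) {
  vapply(name, function(x) {
    x <- gsub("[^A-Za-z0-9]", "", x)
    m <- regmatches(x, regexec("^([0-9]+)([A-Za-z]+)$|^([A-Za-z]+)([0-9]+)$", x))[[1]]
    if (length(m) == 0 || m[1] == "") stop("cannot parse nuclide name: ", x)
    el <- if (m[2] != "") m[3] else m[4]
    a  <- if (m[2] != "") m[2] else m[5]
    paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)), "-", a)
  }, character(1), USE.NAMES = FALSE)
}

new_nuclide <- function(name, half_life_h, emissions, decay_modes, stable) {
  structure(list(name = name, half_life_h = half_life_h,
                 emissions = emissions, decay_modes = decay_modes,
                 stable = stable),
            class = "nuclide")
}

validate_nuclide <- function(nuc) {
  if (!nuc$stable) {
    if (!is.finite(nuc$half_life_h) || nuc$half_life_h <= 0) {
      stop("nuclide ", nuc$name, ": half-life must be > 0")
    }
    bsum <- sum(nuc$decay_modes$branching)
    if (nrow(nuc$decay_modes) > 0 && abs(bsum - 1) > 1e-6) {
      stop("nuclide ", nuc$name, ": branching fractions sum to ", signif(bsum, 6),
           ", not 1 (validation error)")
    }
  }
  em <- nuc$emissions
  if (nrow(em) > 0) {
    if (any(!em$kind %in% EMISSION_KINDS)) {
      stop("nuclide ", nuc$name, ": unknown emission kind: ",
           paste(setdiff(em$kind, EMISSION_KINDS), collapse = ", "))
    }
    if (any(!is.finite(em$energy_mev)) || any(em$energy_mev <= 0)) {
      stop("nuclide ", nuc$name, ": emission energies must be > 0")
    }
    if (any(!is.finite(em$yield)) || any(em$yield < 0)) {
      stop("nuclide ", nuc$name, ": emission yields must be >= 0")
    }
  }
  invisible(nuc)
}

#' Path to the bundled decay-data fixture
#' @return file path of the packaged emission table.
#' @export
tandem_decay_file <- function() {
  system.file("extdata", "decay_emissions.csv", package = "tandemdose",
              mustWork = TRUE)
}

#' Load decay chains from a delimited emission table
#'
#' One emission per row; columns `nuclide, half_life, half_life_unit, daughter,
#' branching, emission_kind, energy_mev, yield`. Stable nuclides appear with
#' `emission_kind = "none"` and empty half-life. Chains are built for every
#' nuclide that is not a daughter of another table entry, and validated:
#' unknown emission kinds are rejected, a daughter missing from the table is a
#' structural error, branching fractions must sum to 1 within 1e-6, and every
#' branch must terminate at a stable nuclide without cycles.
#'
#' @param path delimited text file (default: the bundled fixture).
#' @return named list of `decay_chain` objects keyed by parent nuclide.
#' @examples
#' chains <- load_decay_data()
#' names(chains)
#' length(chains[["Ac-225"]]$members)
#' @export
load_decay_data <- function(path = tandem_decay_file()) {
  tab <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  needed <- c("nuclide", "half_life", "half_life_unit", "daughter",
              "branching", "emission_kind", "energy_mev", "yield")
  if (!all(needed %in% names(tab))) {
    stop("decay table missing columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  tab$half_life <- suppressWarnings(as.numeric(tab$half_life))
  tab$branching <- suppressWarnings(as.numeric(tab$branching))
  tab$energy_mev <- suppressWarnings(as.numeric(tab$energy_mev))
  tab$yield <- suppressWarnings(as.numeric(tab$yield))

  nuclides <- lapply(split(tab, tab$nuclide), function(rows) {
    name <- rows$nuclide[1]
    stable <- all(rows$emission_kind == "none" | !is.finite(rows$half_life))
    em_rows <- rows[rows$emission_kind != "none" & nzchar(rows$emission_kind), , drop = FALSE]
    emissions <- data.frame(kind = em_rows$emission_kind,
                            energy_mev = em_rows$energy_mev,
                            yield = em_rows$yield,
                            stringsAsFactors = FALSE)
    hl <- if (stable) Inf else {
      hls <- unique(to_hours(rows$half_life[is.finite(rows$half_life)],
                             rows$half_life_unit[is.finite(rows$half_life)]))
      if (length(hls) != 1) stop("nuclide ", name, ": inconsistent half-life rows")
      hls
    }
    dm <- unique(data.frame(daughter = rows$daughter, branching = rows$branching,
                            stringsAsFactors = FALSE))
    dm <- dm[!is.na(dm$daughter) & nzchar(dm$daughter) & !is.na(dm$branching), , drop = FALSE]
    validate_nuclide(new_nuclide(name, hl, emissions, dm, stable))
  })

  all_names <- names(nuclides)
  daughters <- unique(unlist(lapply(nuclides, function(n) n$decay_modes$daughter)))
  missing <- setdiff(daughters, all_names)
  if (length(missing) > 0) {
    stop("structural error: daughter nuclide(s) not in table: ",
         paste(missing, collapse = ", "))
  }
  roots <- setdiff(all_names, daughters)
  roots <- roots[!vapply(nuclides[roots], `[[`, logical(1), "stable")]
  chains <- lapply(roots, function(r) build_chain(r, nuclides))
  names(chains) <- roots
  chains
}

# Assemble the reachable sub-DAG from `parent`, checking acyclicity and
# termination, and compute each member's cumulative branch probability.
build_chain <- function(parent, nuclides) {
  order <- character(0)
  onpath <- character(0)
  visit <- function(name) {
    if (name %in% onpath) stop("structural error: decay chain cycle at ", name)
    if (name %in% order) return(invisible())
    onpath <<- c(onpath, name)
    nuc <- nuclides[[name]]
    if (!nuc$stable) {
      if (nrow(nuc$decay_modes) == 0) {
        stop("structural error: radioactive nuclide ", name, " has no decay mode")
      }
      for (d in nuc$decay_modes$daughter) visit(d)
    }
    onpath <<- setdiff(onpath, name)
    order <<- c(order, name)
    invisible()
  }
  visit(parent)
  order <- rev(order)  # parent first, topological
  members <- nuclides[order]

  branch_prob <- setNames(numeric(length(order)), order)
  branch_prob[parent] <- 1
  for (nm in order) {
    nuc <- members[[nm]]
    if (nuc$stable) next
    for (i in seq_len(nrow(nuc$decay_modes))) {
      d <- nuc$decay_modes$daughter[i]
      branch_prob[d] <- branch_prob[d] + branch_prob[nm] * nuc$decay_modes$branching[i]
    }
  }
  structure(list(parent = parent, members = members, order = order,
                 branch_prob = branch_prob),
            class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat("Decay chain of", x$parent, "(", length(x$members), "nuclides )\n")
  for (nm in x$order) {
    n <- x$members[[nm]]
    hl <- if (n$stable) "stable" else sprintf("T1/2 = %.4g h", n$half_life_h)
    cat(sprintf("  %-8s %-16s branch prob %.4f\n", nm, hl, x$branch_prob[nm]))
  }
  invisible(x)
}

#' Half-life and decay constant accessors
#'
#' @param nuclide a `nuclide` object, or a nuclide name resolved against the
#'   bundled decay data.
#' @return half-life in hours, or decay constant in 1/h.
#' @export
half_life_hours <- function(nuclide) {
  nuc <- as_nuclide(nuclide)
  nuc$half_life_h
}

#' @rdname half_life_hours
#' @export
decay_lambda <- function(nuclide) log(2) / half_life_hours(nuclide)

# Resolve a nuclide argument: object passes through, a name is looked up in
# the bundled decay data (cached per session).
as_nuclide <- function(nuclide) {
  if (inherits(nuclide, "nuclide")) return(nuclide)
  name <- normalize_nuclide(nuclide)
  chains <- bundled_chains()
  for (ch in chains) if (name %in% ch$order) return(ch$members[[name]])
  stop("nuclide not found in bundled decay data: ", name)
}

as_chain <- function(chain) {
  if (inherits(chain, "decay_chain")) return(chain)
  name <- normalize_nuclide(chain)
  chains <- bundled_chains()
  if (!name %in% names(chains)) {
    stop("no bundled decay chain rooted at ", name)
  }
  chains[[name]]
}

.tandemdose_cache <- new.env(parent = emptyenv())
bundled_chains <- function() {
  if (is.null(.tandemdose_cache$chains)) {
    .tandemdose_cache$chains <- load_decay_data()
  }
  .tandemdose_cache$chains
}

#' Energy released per disintegration
#'
#' Yield-weighted sum of mean emission energies over emissions passing the
#' filter with yield at or above the cutoff. The default 1% yield cutoff
#' matches the convention used when deriving the reference dose constants.
#'
#' @param nuclide `nuclide` object or name.
#' @param emission_filter filter mode name (see Details) or character vector
#'   of emission kinds. Modes: `reference` (alphas + beta continuum means),
#'   `charged_all`, `beta_continuum_only`, `alpha_only`, `all_photons_only`,
#'   `all`.
#' @param yield_cutoff emissions with yield below this are ignored; in `[0, 1)`.
#' @return MeV per disintegration (0 if nothing passes the filter).
#' @examples
#' energy_per_decay("177Lu", "beta_continuum_only")
#' @export
energy_per_decay <- function(nuclide, emission_filter = "reference",
                             yield_cutoff = 0.01) {
  stopifnot(yield_cutoff >= 0, yield_cutoff < 1)
  nuc <- as_nuclide(nuclide)
  kinds <- resolve_emission_filter(emission_filter)
  em <- nuc$emissions
  keep <- em$kind %in% kinds & em$yield >= yield_cutoff
  sum(em$energy_mev[keep] * em$yield[keep])
}

#' Chain energy per parent disintegration at secular equilibrium
#'
#' Branch-probability-weighted sum of member [energy_per_decay()] values: each
#' chain member contributes its per-decay energy scaled by the cumulative
#' probability that a parent disintegration passes through it (e.g. the Po-213
#' alpha is weighted by the Bi-213 beta-branch fraction).
#'
#' @inheritParams energy_per_decay
#' @param chain `decay_chain` object or parent nuclide name.
#' @return MeV per parent disintegration.
#' @examples
#' chain_energy_per_decay("225Ac")  # ~27.8 MeV in reference mode
#' @export
chain_energy_per_decay <- function(chain, emission_filter = "reference",
                                   yield_cutoff = 0.01) {
  ch <- as_chain(chain)
  sum(vapply(ch$order, function(nm) {
    ch$branch_prob[nm] * energy_per_decay(ch$members[[nm]], emission_filter, yield_cutoff)
  }, numeric(1)))
}

#' Equilibrium dose constant from energy per disintegration
#'
#' Converts MeV released per disintegration into the MIRD-style dose constant
#' Delta in Gy·g/(uCi·h), assuming an absorbed fraction of 1 for the filtered
#' (locally deposited) emissions. The conversion is exact:
#' `E [J/decay] * 3.7e4 decay/(s·uCi) * 3600 s/h / 1e-3 kg/g`.
#'
#' @param energy_mev energy per disintegration in MeV (>= 0).
#' @param emission_filter,yield_cutoff,nuclide_or_chain metadata recorded on
#'   the result.
#' @return a `dose_constant` object with `$value` in Gy·g/(uCi·h).
#' @examples
#' dose_constant(1)$value  # 2.134e-2
#' @export
dose_constant <- function(energy_mev, emission_filter = "reference",
                          yield_cutoff = 0.01, nuclide_or_chain = NA_character_) {
  if (!is.finite(energy_mev) || energy_mev < 0) {
    stop("energy per decay must be >= 0")
  }
  structure(list(value = energy_mev * GYG_PER_UCIH_PER_MEV,
                 energy_mev = energy_mev,
                 emission_filter = emission_filter,
                 yield_cutoff = yield_cutoff,
                 nuclide_or_chain = nuclide_or_chain),
            class = "dose_constant")
}

#' Reference-mode dose constant for a nuclide or chain
#'
#' Convenience wrapper: chain energy (secular equilibrium, branch weighted)
#' piped into [dose_constant()].
#'
#' @inheritParams chain_energy_per_decay
#' @return a `dose_constant`.
#' @examples
#' nuclide_dose_constant("225Ac")$value  # ~0.594
#' nuclide_dose_constant("177Lu")$value  # ~2.86e-3
#' @export
nuclide_dose_constant <- function(chain, emission_filter = "reference",
                                  yield_cutoff = 0.01) {
  ch <- as_chain(chain)
  E <- chain_energy_per_decay(ch, emission_filter, yield_cutoff)
  dose_constant(E, emission_filter, yield_cutoff, ch$parent)
}

#' @export
print.dose_constant <- function(x, ...) {
  cat(sprintf("Dose constant Delta[%s] = %.4e Gy.g/(uCi.h)  (%.4f MeV/decay, filter %s, cutoff %g)\n",
              x$nuclide_or_chain, x$value, x$energy_mev,
              paste(x$emission_filter, collapse = "+"), x$yield_cutoff))
  invisible(x)
}
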