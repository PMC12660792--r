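#' Ballesteros-Weinstein residue maps
#'
#' Class A GPCR residues are conventionally addressed by Ballesteros-Weinstein
#' (BW) codes "X.YY", where X is the transmembrane helix and YY the position
#' relative to the helix's most conserved residue (numbered 50).  A BW map
#' translates such codes into concrete (chain, residue number) pairs of a
#' particular model.  `read_bw_map()` loads a YAML map (one
#' `"X.YY": "chain/resno[/resname]"` entry per code); `gnrh1r_bw_map()`
#' returns the map shipped for the GnRH1 receptor in author numbering (e.g.
#' 3.50 is R139, 6.33 is T265).
#'
#' @param path Path to a YAML BW map file.
#' @return A tibble with columns `bw`, `chain`, `resno`, `resid` (class
#'   `bw_map`).
#' @examples
#' map <- gnrh1r_bw_map()
#' resolve_bw(map, "3.50")
#' @export
read_bw_map <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) abort("empty BW map")
  codes <- names(raw)
  if (!all(grepl("^[0-9]+\\.[0-9]+$", codes))) {
    abort("BW codes must match the pattern 'digit(s).digit(s)'")
  }
  if (anyDuplicated(codes)) abort("BW map codes must be unique")
  parts <- strsplit(vapply(raw, as.character, character(1)), "/", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    abort(sprintf("BW map entry '%s' is not of the form chain/resno[/resname]",
                  codes[which(bad)[1]]))
  }
  out <- tibble(
    bw = codes,
    chain = unname(vapply(parts, `[`, character(1), 1)),
    resno = as.integer(vapply(parts, `[`, character(1), 2)),
    resid = unname(vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                          character(1)))
  )
  if (any(is.na(out$resno)) || any(out$resno < 1)) {
    abort("BW map residue numbers must be positive integers")
  }
  class(out) <- c("bw_map", class(out))
  out
}

#' @rdname read_bw_map
#' @export
gnrh1r_bw_map <- function() {
  read_bw_map(system.file("extdata", "gnrh1r_bw_map.yaml", package = "gnrhkit",
                          mustWork = TRUE))
}

#' Resolve a Ballesteros-Weinstein code to a residue
#'
#' @param map A `bw_map` (see [read_bw_map()]).
#' @param code A BW code such as `"3.50"`.
#' @return One-row tibble with `bw`, `chain`, `resno`, `resid`.
#' @export
resolve_bw <- function(map, code) {
  hit <- map[map$bw == code, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort(sprintf(
      "unknown BW code '%s'; available codes: %s",
      code, paste(map$bw, collapse = ", ")
    ))
  }
  as_tibble(hit[1, ])
}
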