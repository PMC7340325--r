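# Internal helpers shared across modules.

FATE_LEVELS <- c("forebrain", "midbrain", "hindbrain")

cp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cp_error"), call = call))
}

fate_to_int <- function(fate) {
  out <- match(as.character(fate), FATE_LEVELS)
  out[is.na(out)] <- 0L
  as.integer(out)
}

int_to_fate <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- code >= 1L & code <= 3L
  out[ok] <- FATE_LEVELS[code[ok]]
  out
}

# site-indexed state vectors -> canonical cells data.frame
cells_from_vectors <- function(lattice, occupied, producer, content, fate,
                               cell_id) {
  idx <- which(occupied)
  data.frame(
    site = idx,
    x = lattice$centers$x[idx],
    y = lattice$centers$y[idx],
    producer = producer[idx],
    content = content[idx],
    fate = int_to_fate(fate[idx]),
    cell_id = cell_id[idx],
    stringsAsFactors = FALSE
  )
}

# canonical cells data.frame -> site-indexed vectors
vectors_from_cells <- function(lattice, cells) {
  n <- nrow(lattice$centers)
  occupied <- logical(n)
  producer <- logical(n)
  content <- numeric(n)
  fate <- integer(n)
  cell_id <- integer(n)
  occupied[cells$site] <- TRUE
  producer[cells$site] <- cells$producer
  content[cells$site] <- cells$content
  fate[cells$site] <- fate_to_int(cells$fate)
  cell_id[cells$site] <- cells$cell_id
  list(occupied = occupied, producer = producer, content = content,
       fate = fate, cell_id = cell_id)
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    cp_stop(sprintf("`%s` must be a single probability in [0, 1]", name),
            "cp_config_error")
  invisible(p)
}

check_site <- function(lattice, site) {
  n <- nrow(lattice$centers)
  if (!is.numeric(site) || length(site) != 1L || is.na(site) ||
      site < 1 || site > n || site != round(site))
    cp_stop(sprintf("invalid site id (lattice has %d sites)", n),
            "cp_site_error")
  invisible(as.integer(site))
}
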