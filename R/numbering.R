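# RANKL residue numbering differs between species conventions: the rat
# construct numbering runs 2 ahead of mouse and 1 ahead of human
# (rat K182 = mouse K180; rat Q238 = human Q237).  Offsets are fixed
# constants; no alignment is performed.

.species_offset_to_rat <- c(rat = 0L, mouse = 2L, human = 1L)

#' Map a residue number between species numbering conventions
#'
#' Converts a residue number stated in one species' RANKL numbering into
#' another, using the fixed offsets rat = mouse + 2 = human + 1.  The
#' mapping is exactly invertible and composition-consistent.
#'
#' @param resnum residue number (integer, >= 1).
#' @param from,to source and destination species, one of `"rat"`,
#'   `"mouse"`, `"human"`.
#' @return The mapped residue number (integer).
#' @examples
#' map_residue_numbering(182, "rat", "mouse")  # 180
#' map_residue_numbering(238, "rat", "human")  # 237
#' @export
map_residue_numbering <- function(resnum, from, to) {
  from <- match.arg(from, names(.species_offset_to_rat))
  to <- match.arg(to, names(.species_offset_to_rat))
  if (any(resnum < 1) || any(resnum != round(resnum))) {
    stop("resnum must be a positive integer")
  }
  mapped <- as.integer(resnum) + .species_offset_to_rat[[from]] -
    .species_offset_to_rat[[to]]
  if (any(mapped < 1L)) {
    stop("mapped residue number ", mapped[mapped < 1L][1], " is out of range")
  }
  mapped
}
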