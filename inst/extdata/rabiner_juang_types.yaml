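# Rabiner-Juang local continuity constraints, types I..VII.
#
# Each type is a list of productions; each production is an ordered list
# of elementary moves [di, dj] walked from the predecessor cell to the
# current cell. Slope weighting (a: min(di,dj), b: max(di,dj), c: di,
# d: di+dj) is applied per elementary move at pattern-construction time;
# the "smoothed" variant replaces the per-move weights by their mean over
# the production.
#
# Transcribed from the published local-continuity-constraint family used
# by reference DTW implementations. Kept as data (not code) so the table
# can be corrected without touching the algorithm.
type1:
  - [[1, 0]]
  - [[1, 1]]
  - [[0, 1]]
type2:
  - [[1, 1], [1, 0]]
  - [[1, 1]]
  - [[1, 1], [0, 1]]
type3:
  - [[2, 1]]
  - [[1, 1]]
  - [[1, 2]]
type4:
  - [[1, 1], [1, 0]]
  - [[1, 2], [1, 0]]
  - [[1, 1]]
  - [[1, 2]]
type5:
  - [[1, 1], [1, 0], [1, 0]]
  - [[1, 1], [1, 0]]
  - [[1, 1]]
  - [[1, 1], [0, 1]]
  - [[1, 1], [0, 1], [0, 1]]
type6:
  - [[1, 1], [1, 1], [1, 0]]
  - [[1, 1]]
  - [[1, 1], [1, 1], [0, 1]]
type7:
  - [[1, 1], [1, 0], [1, 0]]
  - [[1, 2], [1, 0], [1, 0]]
  - [[1, 3], [1, 0], [1, 0]]
  - [[1, 1], [1, 0]]
  - [[1, 2], [1, 0]]
  - [[1, 3], [1, 0]]
  - [[1, 1]]
  - [[1, 2]]
  - [[1, 3]]
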