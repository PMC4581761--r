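# File format grammars

## PDB subset

`readPDB()` / `writePDB()` handle `ATOM`, `HETATM`, `MODEL`, `ENDMDL`,
`TER` and `END` records with the standard fixed columns:

| columns | field | notes |
|---|---|---|
| 1-6 | record name | `ATOM`/`HETATM` parsed, others skipped |
| 7-11 | serial | integer |
| 13-16 | atom name | names shorter than 4 characters start in column 14 |
| 17 | altLoc | only `'A'` or blank kept; others dropped |
| 18-20 | residue name | |
| 22 | chain id | |
| 23-26 | residue number | |
| 27 | insertion code | part of residue identity |
| 31-54 | x, y, z | `%8.3f` each, Angstrom |
| 77-78 | element | falls back to the first letter of the atom name |

A write/read round trip preserves atom order and coordinates at the
3-decimal PDB precision. Multi-model files are trajectories: one
`MODEL`/`ENDMDL` block per frame, all frames sharing the topology.

## Compact frame format (`.traj`)

```
<n_atoms>                 # line 1: integer atom count
<free-text comment>       # line 2
x y z                     # n_atoms lines per frame, "%.6f %.6f %.6f"
...                       # frames concatenated, no separators
```

The total number of coordinate lines must be an exact multiple of
`n_atoms`; each frame must match the topology atom count.

## Force-field parameter dialect (`.ff`)

Plain text; `#` starts a comment, blank lines ignored. Sections:

```
[atoms]
# chain resseq name charge lj_sigma lj_epsilon gb_radius gb_scale
A 1 N -0.450000 3.250000 0.170000 1.550000 0.790000
...
[bonds]
# i j kb r0              (atom positions, kcal/mol/A^2, A)
[angles]
# i j k ka theta0        (kcal/mol/rad^2, rad)
[dihedrals]
# i j k l barrier periodicity phase   (kcal/mol, integer, rad)
```

Atom entries are keyed by chain / residue number / atom name and must
cover every atom of the structure they parameterize. Bonded-term
indices are 1-based atom positions in the structure's file order and
must lie in range.

## Pipeline configuration (YAML)

See `?runPipeline` for the field list; `toyGlycoformSuite()` writes a
ready-to-run example `config.yaml`.

## Synthetic-spec YAML

Written/read by `writeSyntheticSpec()` / `readSyntheticSpec()`; keys
mirror the `SyntheticSpec` slots in snake_case.
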