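# Data dictionary

## Cell table (per detected cell; CSV with header)

| column         | type      | meaning                                         |
|----------------|-----------|-------------------------------------------------|
| patient_id     | integer   | 1-based patient identifier                      |
| core_id        | character | TMA core identifier within the patient          |
| cell_class     | character | `tumour` or `stroma`                            |
| od_nuclear     | numeric   | mean nuclear DAB optical density, >= 0          |
| od_cytoplasm   | numeric   | mean cytoplasmic DAB optical density, >= 0      |
| od_perinuclear | numeric   | mean perinuclear DAB optical density, >= 0      |
| od_cell        | numeric   | mean whole-cell DAB optical density, >= 0       |

Other export dialects can be mapped onto these names via the `col_map`
argument of `score_cells()`.

## Patient table (per patient; CSV with header)

| column            | type      | meaning                                     |
|-------------------|-----------|---------------------------------------------|
| patient_id        | integer   | 1-based patient identifier                  |
| er_percent        | numeric   | % ER-positive nuclei, 0-100                 |
| er_intensity      | integer   | dominant ER intensity, 0-3                  |
| pr_percent        | numeric   | % PR-positive nuclei, 0-100                 |
| pr_intensity      | integer   | dominant PR intensity, 0-3                  |
| her2_positive     | logical   | HER2 status (ISH/score workflow upstream)   |
| ki67_percent      | numeric   | % Ki67-positive nuclei, 0-100               |
| grade             | character | tumour grade G1/G2/G3                       |
| subtype           | character | St Gallen subtype; derived if absent        |
| top2a             | numeric   | TOP2A % positive tumour nuclei              |
| pten              | numeric   | PTEN nuclear H-score                        |
| egfr              | numeric   | EGFR whole-cell H-score                     |
| igf1r             | numeric   | IGF1R whole-cell H-score                    |
| pmtor_wholecell   | numeric   | p-mTOR whole-cell H-score                   |
| pmtor_perinuclear | numeric   | p-mTOR perinuclear % positive               |
| time              | numeric   | relapse-free survival time, months          |
| event             | integer   | 1 = relapse, 0 = censored                   |

Missing biomarker readouts are empty cells and contribute 0 to the
composite signature score by default.
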