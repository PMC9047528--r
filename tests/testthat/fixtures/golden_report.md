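# Retrosynthesis evaluation (50 test records)

## Top-N accuracy

| N | accuracy |
|---|---|
| top-1 | 50.0% |
| top-3 | 62.0% |
| top-10 | 70.0% |

## Top-N accuracy per reaction class

| class | top1 | top10 |
|---|---|---|
| 1 | 50.0% | 70.0% |
| 2 | 75.0% | 80.0% |

## Grammatical invalidity (rank 1)

Overall: 4.0%

## Failure categories

| structure | count | rate |
|---|---|---|
| R-Boc | 2 | 8.0% |
| R-CF3 | 1 | 4.0% |
| R-tBu | 0 | 0.0% |
| R-fused | 3 | 12.0% |
| R-spiro | 1 | 4.0% |
| R-bridged | 1 | 4.0% |
| Total | 8 | 32.0% |

## Corrected ("true") accuracy

Exact: 50.0%; plausible: 10.0%; corrected top-1: 60.0%

| reaction type | count | rate |
|---|---|---|
| hydrolysis | 5 | 10.0% |
| Total | 5 | 10.0% |
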