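accession_id,total
IRIS_313.8412,14.12
CX237,14.04
IRIS_313.9560,12.64
IRIS_313.11796,12.49
IRIS_313.7778,12.49
IRIS_313.7832,12.48
B051,12.41
IRIS_313.11731,12.32
IRIS_313.10067,12.28
IRIS_313.11297,12.08
IRIS_313.10333,12.05
IRIS_313.11802,12.05
CX225,12.00
IRIS_313.11307,11.50
IRIS_313.11120,11.29
IRIS_313.11261,11.25
IRIS_313.10967,11.04
IRIS_313.10224,11.03
IRIS_313.9922,11.01
IRIS_313.8571,10.75
B043,10.73
IRIS_313.9503,10.73
IRIS_313.11599,10.54
IRIS_313.10430,10.52
IRIS_313.11854,10.42
IRIS_313.10151,10.13
IRIS_313.8641,9.92
IRIS_313.11824,9.74
IRIS_313.9771,9.65
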