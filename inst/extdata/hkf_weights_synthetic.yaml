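intercept: -20.0
terms:
- target: '1'
  weight: 2.0
- target: '2'
  weight: -1.0
- target: '3'
  weight: 1.0
- target: '4'
  weight: 1.0
- target: '6'
  weight: 1.0
- target: '7'
  weight: 1.0
- target: '8'
  weight: -3.0
- target: '9'
  weight: 1.5
- target: '10'
  weight: 1.5
- target: '11'
  weight: 1.5
- target: '12'
  weight: 1.5
- target: '13'
  weight: 1.5
- target: '14'
  weight: 1.2
- target: '15'
  weight: 1.2
- target: '16'
  weight: 1.2
- target: '17'
  weight: 1.2
- target: '18'
  weight: 1.2
- target: '19'
  weight: 0.8
- target: '20'
  weight: 0.8
- target: '21'
  weight: 0.8
- target: '22'
  weight: 0.8
- target: '23'
  weight: 0.8
- target: '24'
  weight: 0.8
- target: '25'
  weight: 0.8
- target: '26'
  weight: 0.8
- target: '27'
  weight: 0.8
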