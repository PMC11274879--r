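>Ab38
DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGG
>Ab40
DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV
>Ab42
DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA
>Ab43
DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIAT
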