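(Oligostraca,((Branchiopoda,(Copepoda,Malacostraca))Vericrustacea,(Collembola,(Diplura,(Archaeognatha,(Zygentoma,(Ephemeroptera,(Odonata,Neoptera))))))Hexapoda)Pancrustacea)Root;
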