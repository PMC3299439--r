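>s1
A--
>s2
-C-
>s3
A--
>s4
---
>s5
---
>s6
--T
>s7
A--
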