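>sp|SYNLACB1|LGB_SYNBOV synthetic beta-lactoglobulin-like OS=Bos taurus
MKTAGELVKTPEVDDEALEKFDKAGSTNVLRQESAGYKVLDTQSAPLKMENSAEPEQK
>sp|SYNLACB2|LGB_SYNOVI synthetic beta-lactoglobulin-like OS=Ovis aries
MKTAGELVKTPEVDNEALEKFDKAGSTNVLRQESAGYKVLDTQSAPLKMENSAEPEQK
>sp|SYNTRI01|AAI_SYNTRI synthetic alpha-amylase-inhibitor-like OS=Triticum aestivum
MASKNVGALLQPGQSYWSTKELAGNDQAVKSGLFDRAPNTQWEKLVSAYESGKQPLNR
>sp|SYNHOM01|KRT_SYNHOM synthetic keratin-like OS=Homo sapiens
MSGSSLGGGFGSRSLYGLGGSKSISISVAGGRAGFGYQESGLSGHEKETMQSLNDRLASYLDK
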