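{"atoms":[{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"},{"element":"C"}],"bonds":[[0,1],[1,2],[2,3],[3,4],[4,5],[0,5],[5,6],[6,7],[7,8],[8,9],[0,9]]}
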