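{
 "summarization_system": "You are an organic chemist summarizing chemical patents.",
 "summarization_user": "Return a short set of three 1\u20133 word descriptors that best describe the chemical or pharmacological function(s) of the molecule described by the given patent title, abstract, and partial description (giving more weight to title and abstract). Be specific and concise, but not necessarily comprehensive (choose a small number of great descriptor). Follow the syntax '{descriptor_1}/{descriptor_2}/{etc}', writing 'NA' if nothing is provided. DO NOT BREAK THIS SYNTAX. The following is the patent:",
 "similarity_system": "You are an organic chemistry expert.",
 "similarity_user": "The following is a set of functional labels for two different molecules. Determine if the two molecules have similar functionality. If similar elements are found in both lists, these molecules have similar function. You must respond in the format '{yes or no} --- {20 word maximum explanation}'"
}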